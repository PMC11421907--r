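# State-space enumeration and the anagenetic/cladogenetic event tables.

## brute-force subset enumeration, independent of the package's ordering
brute_force_states <- function(n, m) {
  out <- list()
  for (mask in 1:(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(members) <= m) out[[length(out) + 1L]] <- members
  }
  out
}

test_that("state enumeration matches brute force for all N <= 8", {
  for (n in 1:8) {
    for (m in seq_len(n)) {
      sp <- state_space(letters[1:n], m)
      bf <- brute_force_states(n, m)
      expect_equal(sp$n_states, length(bf))
      expect_equal(sp$n_states, sum(choose(n, seq_len(m))))
      ## same sets regardless of order
      key <- function(s) paste(sort(s), collapse = "-")
      expect_setequal(vapply(sp$sets, key, ""), vapply(bf, key, ""))
      ## documented order: by size, then bit pattern
      expect_true(all(diff(sp$size) >= 0))
      for (k in unique(sp$size))
        expect_true(all(diff(sp$bits[sp$size == k]) > 0))
    }
  }
  expect_equal(state_space(letters[1:7], 3)$n_states, 63)
  expect_equal(sp2$n_states, 3)
  expect_equal(sp1$n_states, 1)
})

test_that("state space rejects bad input", {
  expect_error(state_space(c("A", "A"), 1), "unique")
  expect_error(state_space(c("A", "B"), 0), "max_range_size")
  expect_error(state_space(c("A", "B"), 3), "max_range_size")
})

test_that("anagenetic table has the GeoSSE structure on two areas", {
  tab <- anagenetic_table(sp2)
  disp <- tab[tab$kind == "dispersal", ]
  ext <- tab[tab$kind == "extirpation", ]
  expect_equal(nrow(disp), 2)
  expect_true(all(disp$to == 3))
  expect_true(all(disp$multiplicity == 1))
  expect_equal(sort(ext$to), c(1, 2))
  expect_true(all(ext$from == 3))
  ## no extirpation out of single-area states
  expect_false(any(ext$from %in% which(sp2$size == 1)))
})

test_that("dispersal multiplicity counts occupied source areas", {
  tab <- anagenetic_table(sp3)
  ab <- state_index(sp3, c("A", "B"))
  abc <- state_index(sp3, c("A", "B", "C"))
  row <- tab[tab$from == ab & tab$to == abc, ]
  expect_equal(nrow(row), 1)
  expect_equal(row$kind, "dispersal")
  expect_equal(row$multiplicity, 2)
  ## every legal gain/loss appears exactly once
  expect_false(any(duplicated(tab[, c("from", "to")])))
  ## gains add one area within the cap, losses remove one without emptying
  for (r in seq_len(nrow(tab))) {
    sz_f <- sp3$size[tab$from[r]]; sz_t <- sp3$size[tab$to[r]]
    if (tab$kind[r] == "dispersal") expect_equal(sz_t, sz_f + 1)
    else { expect_equal(sz_t, sz_f - 1); expect_gte(sz_t, 1) }
  }
})

test_that("DEC cladogenesis: subset sympatry and narrow vicariance", {
  tab <- clado_table(sp3, "DEC")
  abc <- state_index(sp3, c("A", "B", "C"))
  ev <- tab[tab$parent == abc, ]
  is_ev <- ev[ev$kind == "in_situ", ]
  vic <- ev[ev$kind == "vicariance", ]
  expect_equal(nrow(is_ev), 3)
  ## each in-situ pair is (singleton, full range)
  expect_true(all(is_ev$right == abc))
  expect_setequal(is_ev$left, which(sp3$size == 1))
  expect_equal(nrow(vic), 3)
  ## vicariance daughters disjoint, union = parent, one side a singleton
  for (r in seq_len(nrow(vic))) {
    bl <- sp3$bits[vic$left[r]]; br <- sp3$bits[vic$right[r]]
    expect_equal(bitwAnd(bl, br), 0L)
    expect_equal(bl + br, sp3$bits[abc])
    expect_true(min(sp3$size[vic$left[r]], sp3$size[vic$right[r]]) == 1)
  }
  ## singleton parent: exactly one in-situ, no vicariance, in either model
  a <- state_index(sp3, "A")
  for (m in c("DEC", "DIVA")) {
    ev_a <- clado_table(sp3, m)
    ev_a <- ev_a[ev_a$parent == a, ]
    expect_equal(nrow(ev_a), 1)
    expect_equal(ev_a$kind, "in_situ")
    expect_equal(ev_a$left, a); expect_equal(ev_a$right, a)
  }
})

test_that("DIVA cladogenesis: widespread vicariance, no subset sympatry", {
  sp4 <- state_space(c("A", "B", "C", "D"), 4)
  tab <- clado_table(sp4, "DIVA")
  abcd <- state_index(sp4, c("A", "B", "C", "D"))
  ev <- tab[tab$parent == abcd, ]
  expect_true(all(ev$kind == "vicariance"))
  ## includes the AB|CD split as well as A|BCD
  ab <- state_index(sp4, c("A", "B")); cd <- state_index(sp4, c("C", "D"))
  a <- state_index(sp4, "A"); bcd <- state_index(sp4, c("B", "C", "D"))
  key <- paste(ev$left, ev$right)
  expect_true(paste(min(ab, cd), max(ab, cd)) %in% key)
  expect_true(paste(min(a, bcd), max(a, bcd)) %in% key)
  ## 2^(4-1) - 1 = 7 unordered bipartitions
  expect_equal(nrow(ev), 7)
  ## widespread DIVA parents have no in-situ events
  diva3 <- clado_table(sp3, "DIVA")
  wide <- which(sp3$size > 1)
  expect_false(any(diva3$parent %in% wide & diva3$kind == "in_situ"))
})

test_that("DEC and DIVA vicariance coincide for parents of size <= 3", {
  for (sp in list(sp2, sp3, state_space(letters[1:5], 3))) {
    dec <- clado_table(sp, "DEC")
    diva <- clado_table(sp, "DIVA")
    dvic <- dec[dec$kind == "vicariance", c("parent", "left", "right")]
    vvic <- diva[diva$kind == "vicariance", c("parent", "left", "right")]
    expect_equal(dvic[do.call(order, dvic), ], vvic[do.call(order, vvic), ],
                 ignore_attr = TRUE)
    ## the tables differ only by widespread in-situ events
    dis <- dec[dec$kind == "in_situ", ]
    vis <- diva[diva$kind == "in_situ", ]
    expect_setequal(setdiff(dis$parent, vis$parent), which(sp$size > 1))
  }
})

test_that("daughters reconstruct the parent in every cladogenetic event", {
  for (m in c("DEC", "DIVA")) {
    sp <- state_space(letters[1:5], 3)
    tab <- clado_table(sp, m)
    for (r in seq_len(nrow(tab))) {
      u <- bitwOr(sp$bits[tab$left[r]], sp$bits[tab$right[r]])
      expect_equal(u, sp$bits[tab$parent[r]])
      if (tab$kind[r] == "vicariance")
        expect_equal(bitwAnd(sp$bits[tab$left[r]], sp$bits[tab$right[r]]), 0L)
    }
  }
})

test_that("table construction is deterministic", {
  sp <- state_space(letters[1:6], 3)
  expect_identical(anagenetic_table(sp), anagenetic_table(sp))
  expect_identical(clado_table(sp, "DEC"), clado_table(sp, "DEC"))
  expect_identical(state_space(letters[1:6], 3), sp)
})

test_that("parse_range handles labels, 0/1 vectors and errors", {
  iaa <- state_space(c("Borneo", "Sulawesi", "Sumatra", "Java",
                       "Philippines", "NewGuinea", "SEAsia"), 3)
  s <- parse_range("Borneo,Sumatra", iaa)
  expect_equal(iaa$size[s], 2)
  expect_equal(sort(iaa$sets[[s]]), c(1, 3))
  expect_equal(parse_range(" Borneo , Sumatra ", iaa), s)
  expect_equal(parse_range(c(1L, 0L, 1L, 0L, 0L, 0L, 0L), iaa), s)
  expect_error(parse_range("", iaa), "empty range")
  expect_error(parse_range(rep(0L, 7), iaa), "empty range")
  expect_error(parse_range("Atlantis", iaa), "unknown area")
  expect_error(parse_range("Borneo,Sumatra,Java,Sulawesi", iaa), "exceeds")
  expect_error(parse_range(rep(1L, 7), iaa), "exceeds")
})
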