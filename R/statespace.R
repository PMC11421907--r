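#' Geographic range state space
#'
#' Enumerates every non-empty subset of the named areas up to a maximum
#' range size, in a fixed deterministic order (by range size, then by the
#' lexicographic bit pattern of area membership), so that state indices are
#' reproducible across runs and machines. Ranges are encoded as bit patterns
#' over the area ordering: area \code{i} contributes bit \code{2^(i-1)}.
#'
#' @param areas Character vector of unique area labels (e.g. the seven
#'   Indo-Australian Archipelago areas). Order fixes area indices.
#' @param max_range_size Maximum number of areas an ancestral range may
#'   occupy (the cap used in empirical analyses is typically 3).
#' @return An object of class \code{range_space}: a list with elements
#'   \code{areas}, \code{n_areas}, \code{max_range_size}, \code{bits}
#'   (integer bit pattern per state), \code{sets} (list of area index
#'   vectors), \code{size} (range size per state), \code{labels}
#'   (human-readable state labels) and \code{n_states}.
#' @examples
#' sp <- state_space(c("A", "B", "C"), max_range_size = 2)
#' sp$n_states  # 6 = choose(3,1) + choose(3,2)
#' @export
state_space <- function(areas, max_range_size = 3L) {
  areas <- as.character(areas)
  if (length(areas) < 1L) stop("at least one area is required")
  if (anyDuplicated(areas)) stop("area labels must be unique")
  n <- length(areas)
  m <- as.integer(max_range_size)
  if (is.na(m) || m < 1L || m > n)
    stop("max_range_size must be between 1 and the number of areas")

  bits <- integer(0)
  sets <- list()
  for (k in seq_len(m)) {
    combos <- utils::combn(n, k)
    b <- vapply(seq_len(ncol(combos)), function(j)
      sum(bitwShiftL(1L, combos[, j] - 1L)), integer(1))
    o <- order(b)
    bits <- c(bits, b[o])
    sets <- c(sets, lapply(o, function(j) combos[, j]))
  }
  labels <- vapply(sets, function(s) paste(areas[s], collapse = "+"), character(1))
  structure(list(
    areas = areas,
    n_areas = n,
    max_range_size = m,
    bits = bits,
    sets = sets,
    size = lengths(sets),
    labels = labels,
    n_states = length(bits)
  ), class = "range_space")
}

#' @export
print.range_space <- function(x, ...) {
  cat("Range state space:", x$n_areas, "areas, max range size",
      x$max_range_size, "->", x$n_states, "states\n")
  cat("Areas:", paste(x$areas, collapse = ", "), "\n")
  invisible(x)
}

## state index for a bit pattern (0 if absent/illegal)
.state_of_bits <- function(space, b) {
  i <- match(b, space$bits)
  if (is.na(i)) 0L else i
}

#' Look up the state index of a set of areas
#'
#' @param space A \code{range_space}.
#' @param areas Character vector of area labels or integer vector of area
#'   indices.
#' @return Integer state index into \code{space}.
#' @export
state_index <- function(space, areas) {
  if (is.character(areas)) {
    idx <- match(areas, space$areas)
    if (anyNA(idx)) stop("unknown area label(s): ",
                         paste(areas[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(areas)
    if (any(idx < 1L | idx > space$n_areas)) stop("area index out of bounds")
  }
  idx <- unique(idx)
  if (length(idx) == 0L) stop("a range must contain at least one area")
  if (length(idx) > space$max_range_size)
    stop("range of size ", length(idx), " exceeds the cap of ",
         space$max_range_size, " areas")
  b <- sum(bitwShiftL(1L, idx - 1L))
  i <- .state_of_bits(space, b)
  if (i == 0L) stop("range not representable in this state space")
  i
}

#' Parse a textual or 0/1-encoded range
#'
#' Accepts either a delimiter-separated list of area labels
#' (\code{"Borneo,Sumatra"}) or a 0/1 presence vector over the areas, and
#' returns the corresponding state index. Empty ranges and ranges exceeding
#' the size cap are rejected.
#'
#' @param x Character scalar of delimited labels, or a numeric/integer 0/1
#'   vector of length \code{space$n_areas}.
#' @param space A \code{range_space}.
#' @param sep Label delimiter (default comma); surrounding whitespace is
#'   ignored.
#' @return Integer state index.
#' @export
parse_range <- function(x, space, sep = ",") {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    parts <- trimws(strsplit(x, sep, fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0L) stop("empty range: a lineage must occupy at least one area")
    return(state_index(space, parts))
  }
  v <- as.integer(x)
  if (length(v) != space$n_areas)
    stop("presence vector must have one entry per area")
  if (any(is.na(v)) || any(!v %in% c(0L, 1L)))
    stop("presence vector entries must be 0 or 1")
  if (sum(v) == 0L) stop("empty range: a lineage must occupy at least one area")
  state_index(space, which(v == 1L))
}

#' Anagenetic transition table (dispersal and extirpation)
#'
#' Every legal single-area range gain (dispersal / colonization) and
#' single-area range loss (extirpation / local extinction) between states of
#' the space. A dispersal entry from range S to S+{a} carries multiplicity
#' |S|: each occupied area acts as an independent colonization source at the
#' per-pair rate d, following the DEC convention. Extirpation entries carry
#' multiplicity 1 per lost area and only exist for ranges of size >= 2 —
#' a single-area lineage can disappear only through whole-lineage
#' extinction, which is a separate, instantaneous process over the entire
#' range.
#'
#' @param space A \code{range_space}.
#' @return Data frame with columns \code{from}, \code{to} (state indices),
#'   \code{kind} (\code{"dispersal"} or \code{"extirpation"}) and
#'   \code{multiplicity}.
#' @export
anagenetic_table <- function(space) {
  from <- integer(0); to <- integer(0); kind <- character(0); mult <- integer(0)
  for (i in seq_len(space$n_states)) {
    s <- space$sets[[i]]
    k <- length(s)
    if (k < space$max_range_size) {
      for (a in setdiff(seq_len(space$n_areas), s)) {
        j <- .state_of_bits(space, space$bits[i] + bitwShiftL(1L, a - 1L))
        from <- c(from, i); to <- c(to, j)
        kind <- c(kind, "dispersal"); mult <- c(mult, k)
      }
    }
    if (k >= 2L) {
      for (a in s) {
        j <- .state_of_bits(space, space$bits[i] - bitwShiftL(1L, a - 1L))
        from <- c(from, i); to <- c(to, j)
        kind <- c(kind, "extirpation"); mult <- c(mult, 1L)
      }
    }
  }
  data.frame(from = from, to = to, kind = kind, multiplicity = mult,
             stringsAsFactors = FALSE)
}

## all unordered bipartitions (as bit-pattern pairs) of the set encoded by b
.bipartitions <- function(b) {
  members <- which(bitwAnd(b, bitwShiftL(1L, 0:30)) > 0L)
  k <- length(members)
  if (k < 2L) return(list())
  out <- list()
  ## iterate proper non-empty submasks; keep each unordered pair once by
  ## requiring the submask to contain the first member
  first_bit <- bitwShiftL(1L, members[1] - 1L)
  sub <- bitwAnd(b - 1L, b)
  while (sub > 0L) {
    comp <- b - sub
    if (comp > 0L && bitwAnd(sub, first_bit) == first_bit)
      out[[length(out) + 1L]] <- c(sub, comp)
    sub <- bitwAnd(sub - 1L, b)
  }
  out
}

#' Cladogenetic event table for DEC- or DIVA-style speciation
#'
#' Enumerates every allowed cladogenetic event of the model variant as an
#' unordered daughter pair, stored once. In both variants a single-area
#' parent speciates in situ into two copies of itself. Under DEC a
#' widespread parent additionally has one in-situ (subset-sympatry) event
#' per member area, in which one daughter is that single area and the other
#' retains the full parental range, and vicariance is "narrow": one daughter
#' is always a single area, the other the complement. Under DIVA there is no
#' subset sympatry and vicariance is "widespread": any bipartition of the
#' parental range into two non-empty complementary subsets is allowed
#' (e.g. ABCD can split into AB|CD as well as A|BCD).
#'
#' @param space A \code{range_space}.
#' @param model \code{"DEC"} or \code{"DIVA"}.
#' @return Data frame with columns \code{parent}, \code{left}, \code{right}
#'   (state indices, \code{left <= right}), \code{kind} (\code{"in_situ"} or
#'   \code{"vicariance"}) and \code{multiplicity} (always 1; each distinct
#'   event is its own row).
#' @export
clado_table <- function(space, model = c("DEC", "DIVA")) {
  model <- match.arg(model)
  parent <- integer(0); left <- integer(0); right <- integer(0); kind <- character(0)
  add <- function(p, j, k, kd) {
    parent <<- c(parent, p)
    left <<- c(left, min(j, k)); right <<- c(right, max(j, k))
    kind <<- c(kind, kd)
  }
  for (i in seq_len(space$n_states)) {
    s <- space$sets[[i]]
    if (length(s) == 1L) {
      add(i, i, i, "in_situ")
      next
    }
    if (model == "DEC") {
      for (a in s) {
        ja <- .state_of_bits(space, bitwShiftL(1L, a - 1L))
        add(i, ja, i, "in_situ")
      }
    }
    for (bp in .bipartitions(space$bits[i])) {
      sz1 <- sum(bitwAnd(bp[1], bitwShiftL(1L, 0:30)) > 0L)
      sz2 <- sum(bitwAnd(bp[2], bitwShiftL(1L, 0:30)) > 0L)
      if (model == "DEC" && min(sz1, sz2) != 1L) next
      j <- .state_of_bits(space, bp[1]); k <- .state_of_bits(space, bp[2])
      ## daughters of a valid parent are always within the size cap since
      ## they are proper subsets of the parent
      add(i, j, k, "vicariance")
    }
  }
  data.frame(parent = parent, left = left, right = right, kind = kind,
             multiplicity = 1L, stringsAsFactors = FALSE)
}

#' Process rates of the range-diversification model
#'
#' The five rates of the process, all in events per lineage per unit branch
#' time (Myr for a time-calibrated tree in millions of years):
#' \describe{
#'   \item{lambda_is}{in-situ speciation rate, applied per in-situ event
#'     (so a widespread DEC parent of size k has total in-situ rate
#'     \code{k * lambda_is});}
#'   \item{lambda_vic}{vicariant speciation rate, applied per unordered
#'     bipartition event;}
#'   \item{d}{dispersal (colonization) rate per occupied source area and
#'     unoccupied target area;}
#'   \item{e}{extirpation (local extinction) rate per occupied area, active
#'     only for ranges of size >= 2;}
#'   \item{mu}{whole-lineage extinction rate, an instantaneous loss of the
#'     lineage across its entire range. It is always a user-fixed input;
#'     the model never estimates it.}
#' }
#'
#' @param lambda_is,lambda_vic,d,e,mu Non-negative rates.
#' @return An object of class \code{range_rates}.
#' @export
rate_params <- function(lambda_is, lambda_vic, d, e, mu = 0) {
  v <- c(lambda_is = lambda_is, lambda_vic = lambda_vic, d = d, e = e, mu = mu)
  if (any(!is.finite(v)) || any(v < 0)) stop("all rates must be finite and >= 0")
  structure(as.list(v), class = "range_rates")
}

#' @export
print.range_rates <- function(x, ...) {
  cat(sprintf(
    "Rates /lineage/Myr: lambda_is=%.4g lambda_vic=%.4g d=%.4g e=%.4g mu=%.4g\n",
    x$lambda_is, x$lambda_vic, x$d, x$e, x$mu))
  invisible(x)
}
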