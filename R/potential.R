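# Distance-dependent statistical pair potential (DOPE-style).
#
# Atom types are residue identity x {backbone, side-chain centroid} (40 types).
# The potential is a binned -ln(p_obs / p_ref) table: p_obs is the smoothed
# observed distance distribution of each type pair, p_ref the uniform-density
# reference proportional to r^2 within each spherical shell.  Smoothing adds a
# reference-shaped prior with weight `pseudocount`, which makes the table
# exactly invariant under duplication of the training corpus.

.PP_TYPES <- as.vector(t(outer(.AA1, c("bb", "cen"), paste, sep = ":")))

.pp_type_id <- function(aa, is_cen) {
  (match(aa, .AA1) - 1L) * 2L + 1L + as.integer(is_cen)
}

# flat atom arrays for pair scoring
.scoring_arrays <- function(s) {
  stopifnot(inherits(s, "zipper_structure"))
  res_key <- paste(s$chain, s$resno, sep = "\r")
  res_uid <- match(res_key, unique(res_key))
  if (anyNA(s$aa)) stop("structure must be sanitized before scoring")
  list(coords = as.matrix(s[, c("x", "y", "z")]),
       type = .pp_type_id(s$aa, s$atom == "CEN"),
       res_uid = res_uid,
       chain = match(s$chain, unique(s$chain)),
       resno = s$resno)
}

# qualifying residue pairs: sequence separation >= 2 within a chain, or any
# inter-chain pair.  Returns i/j index vectors (i < j).
.pair_indices <- function(chain, resno, res_uid) {
  m <- length(chain)
  qual <- (outer(chain, chain, "!=") |
             abs(outer(resno, resno, "-")) >= 2) &
    outer(res_uid, res_uid, "!=")
  qual[lower.tri(qual, diag = TRUE)] <- FALSE
  idx <- which(qual, arr.ind = TRUE)
  list(i = idx[, 1], j = idx[, 2])
}

#' Train a distance-dependent statistical pair potential
#'
#' Counts all qualifying inter-residue atom-pair distances in the training
#' structures (sequence separation >= 2 within a chain; all inter-chain
#' pairs), smooths each type pair's distance distribution toward the r^2
#' reference with prior weight `pseudocount`, and returns per-bin
#' `-ln(p_obs / p_ref)` scores.
#'
#' @param structures list of sanitized `zipper_structure` objects.
#' @param bins strictly increasing distance bin edges (Angstrom).
#' @param cutoff maximum counted distance (must not exceed the last edge).
#' @param pseudocount non-negative prior weight of the reference density.
#' @return object of class `pair_potential` with fields `atom_types`,
#'   `bin_edges`, `scores` (type x type x bin array) and `cutoff`.
#' @export
train_pair_potential <- function(structures, bins = seq(0, 15, by = 0.5),
                                 cutoff = 15, pseudocount = 1) {
  if (!is.list(structures) || length(structures) == 0) {
    stop("need at least one training structure")
  }
  if (any(diff(bins) <= 0)) stop("bin edges must be strictly increasing")
  if (cutoff > bins[length(bins)]) stop("cutoff exceeds the last bin edge")
  K <- length(bins) - 1L
  nt <- length(.PP_TYPES)
  counts <- array(0, dim = c(nt, nt, K))
  for (s in structures) {
    arr <- .scoring_arrays(s)
    pr <- .pair_indices(arr$chain, arr$resno, arr$res_uid)
    d <- sqrt(rowSums((arr$coords[pr$i, , drop = FALSE] -
                         arr$coords[pr$j, , drop = FALSE])^2))
    keep <- d < cutoff & d >= bins[1]
    if (!any(keep)) next
    bin <- findInterval(d[keep], bins, rightmost.closed = TRUE)
    ta <- pmin(arr$type[pr$i][keep], arr$type[pr$j][keep])
    tb <- pmax(arr$type[pr$i][keep], arr$type[pr$j][keep])
    tab <- table(factor(ta, levels = seq_len(nt)),
                 factor(tb, levels = seq_len(nt)),
                 factor(bin, levels = seq_len(K)))
    counts <- counts + as.numeric(tab)
  }
  # reference: uniform density within the cutoff sphere, per-shell mass ~ r^2 dr
  hi <- pmin(bins[-1], cutoff)
  lo <- bins[-length(bins)]
  w <- pmax(hi^3 - lo^3, 0)
  p_ref <- w / sum(w)
  scores <- array(0, dim = c(nt, nt, K))
  for (a in seq_len(nt)) {
    for (b in a:nt) {
      n_k <- counts[a, b, ]
      N <- sum(n_k)
      if (N > 0) {
        p_obs <- (n_k + pseudocount * N * p_ref) / (N * (1 + pseudocount))
        sc <- -log(p_obs / p_ref)
        scores[a, b, ] <- sc
        scores[b, a, ] <- sc
      }
    }
  }
  structure(list(atom_types = .PP_TYPES, bin_edges = bins, scores = scores,
                 cutoff = cutoff, pseudocount = pseudocount),
            class = "pair_potential")
}

#' @export
print.pair_potential <- function(x, ...) {
  cat("pair_potential: ", length(x$atom_types), " atom types, ",
      length(x$bin_edges) - 1, " bins to ", x$cutoff, " Angstrom\n", sep = "")
  invisible(x)
}

#' Score a model with a trained pair potential
#'
#' Sums the per-bin scores of every qualifying atom pair (sequence separation
#' >= 2 within a chain, all inter-chain pairs) within the table's cutoff;
#' pairs beyond the cutoff contribute zero.  Lower is more stable.
#'
#' @param model a sanitized `zipper_structure`.
#' @param table a [train_pair_potential()] table.
#' @return numeric score.
#' @export
dope_score <- function(model, table) {
  stopifnot(inherits(table, "pair_potential"))
  arr <- .scoring_arrays(model)
  missing_types <- setdiff(.PP_TYPES[unique(arr$type)], table$atom_types)
  if (length(missing_types) > 0) {
    stop("unknown atom type(s) not in the potential table: ",
         paste(missing_types, collapse = ", "))
  }
  type_idx <- match(.PP_TYPES, table$atom_types)[arr$type]
  pr <- .pair_indices(arr$chain, arr$resno, arr$res_uid)
  d <- sqrt(rowSums((arr$coords[pr$i, , drop = FALSE] -
                       arr$coords[pr$j, , drop = FALSE])^2))
  keep <- d < table$cutoff & d >= table$bin_edges[1]
  if (!any(keep)) return(0)
  bin <- findInterval(d[keep], table$bin_edges, rightmost.closed = TRUE)
  sum(table$scores[cbind(type_idx[pr$i][keep], type_idx[pr$j][keep], bin)])
}

#' Default pair potential trained on the idealized template library
#'
#' The training corpus is the seven confirmed-class idealized templates
#' threaded with their native sequences (self-contained, deterministic).
#' The result is cached for the session.
#'
#' @return a `pair_potential`.
#' @export
default_pair_potential <- function() {
  if (is.null(.zipthread_env$default_potential)) {
    lib <- template_library()
    .zipthread_env$default_potential <-
      train_pair_potential(lapply(lib, `[[`, "structure"))
  }
  .zipthread_env$default_potential
}

#' Write a pair potential as a plain-text table
#'
#' @param table a `pair_potential`.
#' @param path output TSV path (columns type_a, type_b, bin_lo, bin_hi, score).
#' @return `path`, invisibly.
#' @export
write_pair_potential <- function(table, path) {
  stopifnot(inherits(table, "pair_potential"))
  nt <- length(table$atom_types)
  K <- length(table$bin_edges) - 1L
  grid <- expand.grid(a = seq_len(nt), b = seq_len(nt), k = seq_len(K))
  grid <- grid[grid$a <= grid$b, , drop = FALSE]
  df <- data.frame(
    type_a = table$atom_types[grid$a],
    type_b = table$atom_types[grid$b],
    bin_lo = table$bin_edges[grid$k],
    bin_hi = table$bin_edges[grid$k + 1L],
    score = table$scores[cbind(grid$a, grid$b, grid$k)]
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pair potential written by [write_pair_potential()]
#'
#' @param path TSV path.
#' @param cutoff,pseudocount metadata not stored in the table body.
#' @return a `pair_potential`.
#' @export
read_pair_potential <- function(path, cutoff = NULL, pseudocount = NA) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  types <- unique(c(df$type_a, df$type_b))
  # preserve canonical ordering where possible
  types <- c(intersect(.PP_TYPES, types), setdiff(types, .PP_TYPES))
  edges <- sort(unique(c(df$bin_lo, df$bin_hi)))
  K <- length(edges) - 1L
  nt <- length(types)
  scores <- array(0, dim = c(nt, nt, K))
  a <- match(df$type_a, types)
  b <- match(df$type_b, types)
  k <- match(df$bin_lo, edges[-length(edges)])
  scores[cbind(a, b, k)] <- df$score
  scores[cbind(b, a, k)] <- df$score
  if (is.null(cutoff)) cutoff <- max(edges)
  structure(list(atom_types = types, bin_edges = edges, scores = scores,
                 cutoff = cutoff, pseudocount = pseudocount),
            class = "pair_potential")
}
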