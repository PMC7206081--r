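# Threading engine: graft a query sequence onto class templates, generate
# stochastic decoys, and select the lowest-scoring model.
#
# The backbone is never moved: decoy variability comes from seeded Gaussian
# jitter of the side-chain centroid pseudo-atoms plus a small rigid-body
# rotation/translation of the second sheet's centroids about the fibril axis.
# Decoy 0 of every class is the unperturbed graft.

.DECOY_JITTER_SD <- 0.3      # Angstrom, per centroid coordinate
.DECOY_ROT_MAX <- 5          # degrees, sheet-B rotation about the fibril axis
.DECOY_TRANS_MAX <- 0.5      # Angstrom, sheet-B shift along the sheet normal

.decoy_seed <- function(seed, class_id, decoy_index) {
  (as.integer(seed) + 1000L * as.integer(class_id) +
     as.integer(decoy_index)) %% 2147483647L
}

.check_query <- function(query, template) {
  aa <- .aa_check(query)
  len <- max(template$scaffold$res$resno)
  if (length(aa) != len) {
    stop("query length (", length(aa), ") does not match template peptide length (",
         len, ")")
  }
  aa
}

#' Thread a query sequence onto a zipper template
#'
#' Replaces every chain's residue identities by the query (position 1..L along
#' each strand's own N-to-C direction), keeps the backbone untouched, and
#' rebuilds CB and side-chain centroid pseudo-atoms for the new identities
#' (glycine carries neither).
#'
#' @param query one-letter peptide sequence matching the template length.
#' @param template a `zipper_template`.
#' @return a `zipper_structure` of the threaded model.
#' @export
graft <- function(query, template) {
  stopifnot(inherits(template, "zipper_template"))
  aa <- .check_query(query, template)
  .scaffold_structure(template$scaffold, aa,
                      metadata = list(class_id = template$spec$class_id,
                                      query = query,
                                      source = template$source))
}

# Flat arrays of a grafted model for fast scoring: atoms blocked by kind
# (all N, all CA, all C, all O, CB of non-Gly, CEN of non-Gly).
.graft_arrays <- function(template, aa) {
  sc <- template$scaffold
  res <- sc$res
  n <- nrow(res)
  res_aa <- aa[res$resno]
  side <- which(res_aa != "G")
  u <- (sc$CBv - sc$CA) / sqrt(rowSums((sc$CBv - sc$CA)^2))
  cen <- sc$CA[side, , drop = FALSE] +
    u[side, , drop = FALSE] * .CEN_DIST[res_aa[side]]
  coords <- rbind(sc$N, sc$CA, sc$C, sc$O,
                  sc$CBv[side, , drop = FALSE], cen)
  res_of <- c(rep(seq_len(n), 4), side, side)
  kind <- c(rep(c("N", "CA", "C", "O"), each = n),
            rep("CB", length(side)), rep("CEN", length(side)))
  m <- length(res_of)
  cen_rows <- (m - length(side) + 1L):m
  list(coords = coords,
       kind = kind,
       aa = res_aa[res_of],
       res_uid = res_of,
       chain = match(res$chain, sc$chain_ids)[res_of],
       resno = res$resno[res_of],
       sheet = res$sheet[res_of],
       type = .pp_type_id(res_aa[res_of], kind == "CEN"),
       cen_rows = cen_rows,
       cen_res = side,
       n_res = n)
}

# Closure scoring a model given its centroid coordinates; the backbone
# contribution and pair bookkeeping are precomputed.
.make_decoy_scorer <- function(arr, potential, margin = 3) {
  edges <- potential$bin_edges
  cutoff <- potential$cutoff
  nt <- length(potential$atom_types)
  type <- match(.PP_TYPES, potential$atom_types)[arr$type]
  if (anyNA(type[unique(arr$res_uid) > 0])) stop("unknown atom type in potential")
  pr <- .pair_indices(arr$chain, arr$resno, arr$res_uid)
  is_cen <- seq_len(nrow(arr$coords)) %in% arr$cen_rows
  cen_pair <- is_cen[pr$i] | is_cen[pr$j]

  pdist <- function(i, j, X) {
    sqrt((X[i, 1] - X[j, 1])^2 + (X[i, 2] - X[j, 2])^2 + (X[i, 3] - X[j, 3])^2)
  }
  # constant backbone-backbone part
  bi <- pr$i[!cen_pair]; bj <- pr$j[!cen_pair]
  db <- pdist(bi, bj, arr$coords)
  keep <- db < cutoff & db >= edges[1]
  const_score <- if (any(keep)) {
    bin <- findInterval(db[keep], edges, rightmost.closed = TRUE)
    sum(potential$scores[cbind(type[bi][keep], type[bj][keep], bin)])
  } else 0
  # centroid-involving pairs, prefiltered by unperturbed distance
  ci <- pr$i[cen_pair]; cj <- pr$j[cen_pair]
  d0 <- pdist(ci, cj, arr$coords)
  near <- d0 < cutoff + margin
  ci <- ci[near]; cj <- cj[near]
  flat_base <- type[ci] + (type[cj] - 1L) * nt
  scores_flat <- as.vector(potential$scores)
  lo <- edges[1]
  function(coords) {
    d <- pdist(ci, cj, coords)
    keep <- d < cutoff & d >= lo
    if (!any(keep)) return(const_score)
    bin <- findInterval(d[keep], edges, rightmost.closed = TRUE)
    const_score + sum(scores_flat[flat_base[keep] + (bin - 1L) * nt * nt])
  }
}

# perturbed centroid coordinates for one decoy (decoy 0 is unperturbed)
.perturb_centroids <- function(arr, template, decoy_index, stream_seed) {
  coords <- arr$coords
  if (decoy_index == 0) return(coords)
  cen_rows <- arr$cen_rows
  ncen <- length(cen_rows)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(stream_seed)
  jit <- matrix(stats::rnorm(3 * ncen, sd = .DECOY_JITTER_SD), ncol = 3)
  cen <- coords[cen_rows, , drop = FALSE] + jit
  # rigid-body motion of sheet-B centroids about the fibril axis
  ang <- stats::runif(1, -.DECOY_ROT_MAX, .DECOY_ROT_MAX)
  tr <- stats::runif(1, -.DECOY_TRANS_MAX, .DECOY_TRANS_MAX)
  in_b <- arr$sheet[cen_rows] == "B"
  if (any(in_b)) {
    frame <- template$scaffold$frame
    bb_b <- arr$coords[arr$sheet == "B" & arr$kind == "CA", , drop = FALSE]
    pivot <- colMeans(bb_b)
    R <- .rotmat(frame$fibril_axis, ang)
    moved <- sweep(cen[in_b, , drop = FALSE], 2, pivot) %*% t(R)
    moved <- sweep(moved, 2, pivot, "+")
    moved <- sweep(moved, 2, tr * frame$sheet_normal, "+")
    cen[in_b, ] <- moved
  }
  coords[cen_rows, ] <- cen
  coords
}

# materialize a zipper_structure for a decoy from its perturbed coordinates
.decoy_structure <- function(template, aa, arr, coords, query) {
  s <- .scaffold_structure(template$scaffold, aa,
                           metadata = list(class_id = template$spec$class_id,
                                           query = query,
                                           source = template$source))
  cen_idx <- which(s$atom == "CEN")
  # CEN rows in `s` follow residue order, as do arr$cen_rows
  s$x[cen_idx] <- coords[arr$cen_rows, 1]
  s$y[cen_idx] <- coords[arr$cen_rows, 2]
  s$z[cen_idx] <- coords[arr$cen_rows, 3]
  s
}

#' Generate and score threaded decoys for a query over a template library
#'
#' For every template, produces `decoys_per_class` models: decoy 0 is the
#' unperturbed graft; subsequent decoys add seeded Gaussian jitter to the
#' side-chain centroids and a small rigid-body perturbation of the second
#' sheet's centroids.  Every decoy is scored with the statistical potential
#' and the global minimum is selected (ties broken by lower class id, then
#' lower decoy index).
#'
#' @param query one-letter peptide sequence.
#' @param templates list of `zipper_template` objects (e.g.
#'   [template_library()]); all must match the query length.
#' @param decoys_per_class models per structural class.
#' @param seed master seed; per-decoy streams are derived as
#'   `seed + 1000 * class_id + decoy_index`.
#' @param potential a `pair_potential` (defaults to the library-trained one).
#' @param keep_models if `FALSE`, only the best decoy's structure is
#'   materialized (faster for batch featurization).
#' @return object of class `threading_result`: list with `query`, `decoys`
#'   (each a list with `class_id`, `decoy_index`, `dope_like`, `seed`,
#'   `model`) and `best`.
#' @export
generate_decoys <- function(query, templates, decoys_per_class = 10, seed = 1,
                            potential = default_pair_potential(),
                            keep_models = TRUE) {
  if (!is.list(templates) || length(templates) == 0) {
    stop("need at least one template")
  }
  decoys <- vector("list", length(templates) * decoys_per_class)
  pos <- 0L
  best_i <- NA_integer_
  best_key <- c(Inf, Inf, Inf)
  best_coords <- NULL
  best_arr <- NULL
  best_template <- NULL
  best_aa <- NULL
  for (tmpl in templates) {
    aa <- .check_query(query, tmpl)
    arr <- .graft_arrays(tmpl, aa)
    scorer <- .make_decoy_scorer(arr, potential)
    cid <- tmpl$spec$class_id
    for (d in seq_len(decoys_per_class) - 1L) {
      stream <- .decoy_seed(seed, cid, d)
      coords <- .perturb_centroids(arr, tmpl, d, stream)
      sc <- scorer(coords)
      pos <- pos + 1L
      decoys[[pos]] <- list(
        class_id = cid, decoy_index = d, dope_like = sc, seed = stream,
        model = if (keep_models) .decoy_structure(tmpl, aa, arr, coords, query)
      )
      key <- c(sc, cid, d)
      if (key[1] < best_key[1] ||
          (key[1] == best_key[1] && (key[2] < best_key[2] ||
            (key[2] == best_key[2] && key[3] < best_key[3])))) {
        best_key <- key
        best_i <- pos
        best_coords <- coords
        best_arr <- arr
        best_template <- tmpl
        best_aa <- aa
      }
    }
  }
  best <- decoys[[best_i]]
  if (is.null(best$model)) {
    best$model <- .decoy_structure(best_template, best_aa, best_arr,
                                   best_coords, query)
  }
  structure(list(query = query, decoys = decoys, best = best),
            class = "threading_result")
}

#' @export
print.threading_result <- function(x, ...) {
  cat("threading_result: query ", x$query, ", ", length(x$decoys),
      " decoys; best: class ", x$best$class_id, " decoy ",
      x$best$decoy_index, " (score ", signif(x$best$dope_like, 6), ")\n",
      sep = "")
  invisible(x)
}

#' Export a threading result as a TSV table
#'
#' @param result a `threading_result`.
#' @param path output path; columns query, class_id, decoy_index, dope_like,
#'   is_best.
#' @return `path`, invisibly.
#' @export
write_threading_tsv <- function(result, path) {
  stopifnot(inherits(result, "threading_result"))
  df <- data.frame(
    query = result$query,
    class_id = vapply(result$decoys, `[[`, numeric(1), "class_id"),
    decoy_index = vapply(result$decoys, `[[`, numeric(1), "decoy_index"),
    dope_like = vapply(result$decoys, `[[`, numeric(1), "dope_like")
  )
  df$is_best <- df$class_id == result$best$class_id &
    df$decoy_index == result$best$decoy_index
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
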