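# Synthetic labeled peptides and toy structures.
#
# The generator emulates the statistical shape of the experimental hexapeptide
# classification data: a 244:836 amyloid / non-amyloid imbalance and a
# composition bias of the positives toward high beta-propensity, hydrophobic
# residues (V, I, F, L, Y, T).  The bias is an exponential tilt of the
# residue sampling distribution with a single strength knob (`effect_size`);
# at zero the two classes are compositionally indistinguishable.

#' Configuration for the synthetic peptide generator
#'
#' @param n number of peptides.
#' @param positive_fraction fraction labeled amyloid; the default mirrors the
#'   244:836 imbalance of experimental hexapeptide collections.
#' @param effect_size non-negative strength of the composition bias.
#' @param length peptide length (4 to 10).
#' @param seed RNG seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n = 1080, positive_fraction = 244 / 1080,
                             effect_size = 1.0, length = 6, seed = 1) {
  stopifnot(n >= 2, positive_fraction > 0, positive_fraction < 1,
            effect_size >= 0, length >= 4, length <= 10)
  structure(list(n = n, positive_fraction = positive_fraction,
                 effect_size = effect_size, length = length, seed = seed),
            class = "generator_config")
}

#' Generate a labeled synthetic peptide dataset
#'
#' Positives are sampled from a residue distribution tilted by
#' `exp(+effect_size * propensity)`, negatives by the complementary tilt
#' `exp(-effect_size * propensity)`, where the propensity table favors
#' V, I, F, L, Y and T.  Sequences are unique and label counts are exact
#' (`round(n * positive_fraction)` positives).
#'
#' @param cfg a [generator_config()].
#' @return a [labeled_dataset()] with columns `sequence` and `label`
#'   (features unset).
#' @export
generate_peptides <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  capacity <- 20^cfg$length
  if (cfg$n > capacity * 0.5) {
    stop("n too large to draw unique sequences of length ", cfg$length)
  }
  n_pos <- round(cfg$n * cfg$positive_fraction)
  n_neg <- cfg$n - n_pos
  w_pos <- exp(cfg$effect_size * .BETA_PROP[.AA1])
  w_neg <- exp(-cfg$effect_size * .BETA_PROP[.AA1])
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)
  draw <- function(k, w, taken) {
    out <- character(0)
    while (length(out) < k) {
      need <- k - length(out)
      seqs <- vapply(seq_len(need * 2), function(i) {
        paste(sample(.AA1, cfg$length, replace = TRUE, prob = w),
              collapse = "")
      }, character(1))
      seqs <- setdiff(unique(seqs), c(taken, out))
      out <- c(out, head(seqs, need))
    }
    out
  }
  pos <- draw(n_pos, w_pos, character(0))
  neg <- draw(n_neg, w_neg, pos)
  labeled_dataset(c(pos, neg),
                  c(rep("amyloid", n_pos), rep("non-amyloid", n_neg)),
                  provenance = sprintf(
                    "synthetic: n=%d pos_frac=%.4f effect=%.2f len=%d seed=%d",
                    cfg$n, cfg$positive_fraction, cfg$effect_size,
                    cfg$length, cfg$seed))
}

#' Generate toy zipper structures
#'
#' Idealized templates threaded with random sequences; every even-indexed
#' structure is a centroid-perturbed variant of its predecessor (identical
#' backbone, jittered side-chain centroids).  Deterministic given the seed.
#'
#' @param n number of structures.
#' @param seed RNG seed.
#' @param peptide_length strand length.
#' @return list of `zipper_structure` objects.
#' @export
generate_toy_structures <- function(n, seed = 1, peptide_length = 6) {
  stopifnot(n >= 1)
  lib <- template_library(peptide_length = peptide_length)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (i %% 2 == 0) {
      parent <- out[[i - 1]]
      s <- parent
      cen <- which(s$atom == "CEN")
      jit <- matrix(stats::rnorm(3 * length(cen), sd = .DECOY_JITTER_SD),
                    ncol = 3)
      s$x[cen] <- s$x[cen] + jit[, 1]
      s$y[cen] <- s$y[cen] + jit[, 2]
      s$z[cen] <- s$z[cen] + jit[, 3]
      md <- attr(s, "metadata")
      md$perturbed <- TRUE
      attr(s, "metadata") <- md
      out[[i]] <- s
    } else {
      tmpl <- lib[[(i - 1) %% length(lib) + 1]]
      query <- paste(sample(.AA1, peptide_length, replace = TRUE),
                     collapse = "")
      out[[i]] <- graft(query, tmpl)
    }
  }
  out
}

#' Write peptide sequences as FASTA
#'
#' @param d a `labeled_dataset` (or any data.frame with `sequence`; labels,
#'   when present, go into the headers).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(d, path) {
  df <- as.data.frame(d)
  names_out <- if ("label" %in% names(df)) {
    paste0("pep", seq_len(nrow(df)), "|", df$label)
  } else {
    paste0("pep", seq_len(nrow(df)))
  }
  seqinr::write.fasta(as.list(df$sequence), names_out, path, as.string = TRUE)
  invisible(path)
}

#' Read peptide sequences from FASTA or plain text
#'
#' Plain-text input holds one sequence per line; FASTA is detected by a
#' leading `>`.  Sequences are upper-cased; validation is left to the
#' consumer so that invalid entries can be reported per sequence.
#'
#' @param path input path.
#' @return character vector of sequences, named by FASTA headers when
#'   available.
#' @export
read_peptides <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  if (length(first) == 0) stop("empty input file: ", path)
  if (startsWith(first, ">")) {
    fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
    stats::setNames(toupper(unlist(fa)), names(fa))
  } else {
    x <- trimws(readLines(path, warn = FALSE))
    toupper(x[nzchar(x)])
  }
}
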