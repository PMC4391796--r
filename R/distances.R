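#' Kimura two-parameter distance for one aligned pair
#'
#' Compares two equal-length aligned sequences over the columns where both
#' carry an unambiguous base (A/C/G/T); gaps and IUPAC ambiguity codes are
#' dropped pairwise. With `P` the transition proportion (A<->G, C<->T) and
#' `Q` the transversion proportion over the `n_sites` compared columns, the
#' corrected distance is
#' `d = -1/2 * log(1 - 2P - Q) - 1/4 * log(1 - 2Q)`.
#' When the correction is undefined (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`,
#' i.e. saturation) or no sites are comparable, `d` is `NA` and the pair is
#' flagged undefined rather than given a fabricated value.
#'
#' @param a,b Character vectors of single residues (rows of an
#'   [aligned_set()] matrix) or single strings of equal length.
#' @return A list with `d` (proportion), `P`, `Q`, `p` (uncorrected
#'   p-distance), `n_sites`, and `defined` (logical).
#' @export
k2p_pair <- function(a, b) {
  if (length(a) == 1L && nchar(a[1]) > 1L) a <- strsplit(a, "")[[1]]
  if (length(b) == 1L && nchar(b[1]) > 1L) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b)) stop("unaligned pair: lengths differ")
  a <- toupper(a); b <- toupper(b)
  acgt <- c("A", "C", "G", "T")
  use <- a %in% acgt & b %in% acgt
  n <- sum(use)
  if (n == 0L) {
    return(list(d = NA_real_, P = NA_real_, Q = NA_real_, p = NA_real_,
                n_sites = 0L, defined = FALSE))
  }
  aa <- a[use]; bb <- b[use]
  diff <- aa != bb
  # purine<->purine or pyrimidine<->pyrimidine mismatches are transitions
  pur_a <- aa %in% c("A", "G"); pur_b <- bb %in% c("A", "G")
  ts <- sum(diff & (pur_a == pur_b))
  tv <- sum(diff & (pur_a != pur_b))
  P <- ts / n; Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(d = NA_real_, P = P, Q = Q, p = P + Q,
                n_sites = n, defined = FALSE))
  }
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  list(d = d, P = P, Q = Q, p = P + Q, n_sites = n, defined = TRUE)
}

#' Pairwise K2P distance matrix
#'
#' Applies [k2p_pair()] to every pair of an [aligned_set()]. Under
#' `"pairwise_deletion"` (default) each pair drops only its own gap or
#' ambiguous columns; under `"complete_deletion"` every column containing a
#' non-ACGT symbol in any sequence is removed once for all pairs.
#' Saturated or incomparable pairs carry `NA` in the distance matrix and are
#' listed in `undefined_pairs`; they are never imputed.
#'
#' @param aligned An [aligned_set()] with at least 2 records.
#' @param gap_mode `"pairwise_deletion"` or `"complete_deletion"`.
#' @return An object of class `dist_matrix`: list with `ids`, `d`
#'   (symmetric numeric matrix, zero diagonal, proportions), `P`, `Q`,
#'   `usable_sites` (integer matrix) and `undefined_pairs` (two-column id
#'   matrix, possibly empty).
#' @export
k2p_matrix <- function(aligned,
                       gap_mode = c("pairwise_deletion", "complete_deletion")) {
  stopifnot(inherits(aligned, "aligned_set"))
  gap_mode <- match.arg(gap_mode)
  n <- length(aligned$ids)
  if (n < 2) stop("need at least 2 sequences for a distance matrix")
  mat <- aligned$mat
  if (gap_mode == "complete_deletion") {
    keep <- apply(mat, 2, function(col) all(col %in% c("A", "C", "G", "T")))
    if (!any(keep)) stop("no columns survive complete deletion")
    mat <- mat[, keep, drop = FALSE]
  }
  # integer-encode once: A=1 C=2 G=3 T=4, others NA
  enc <- matrix(match(mat, c("A", "C", "G", "T")), nrow = n)
  ids <- aligned$ids
  d <- P <- Q <- matrix(0, n, n, dimnames = list(ids, ids))
  ns <- matrix(ncol(mat), n, n, dimnames = list(ids, ids))
  undef <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  purine <- c(TRUE, FALSE, TRUE, FALSE) # A, C, G, T
  for (i in seq_len(n - 1)) {
    ei <- enc[i, ]
    for (j in (i + 1):n) {
      ej <- enc[j, ]
      use <- !is.na(ei) & !is.na(ej)
      nij <- sum(use)
      if (nij == 0L) {
        d[i, j] <- d[j, i] <- NA_real_
        P[i, j] <- P[j, i] <- NA_real_
        Q[i, j] <- Q[j, i] <- NA_real_
        ns[i, j] <- ns[j, i] <- 0L
        undef[i, j] <- undef[j, i] <- TRUE
        next
      }
      ai <- ei[use]; aj <- ej[use]
      diff <- ai != aj
      same_class <- purine[ai] == purine[aj]
      p_ <- sum(diff & same_class) / nij
      q_ <- sum(diff & !same_class) / nij
      ns[i, j] <- ns[j, i] <- nij
      P[i, j] <- P[j, i] <- p_
      Q[i, j] <- Q[j, i] <- q_
      w1 <- 1 - 2 * p_ - q_
      w2 <- 1 - 2 * q_
      if (w1 <= 0 || w2 <= 0) {
        d[i, j] <- d[j, i] <- NA_real_
        undef[i, j] <- undef[j, i] <- TRUE
      } else {
        d[i, j] <- d[j, i] <- -0.5 * log(w1) - 0.25 * log(w2)
      }
    }
  }
  und <- which(undef & upper.tri(undef), arr.ind = TRUE)
  undefined_pairs <- cbind(ids[und[, 1]], ids[und[, 2]])
  if (nrow(und) == choose(n, 2)) stop("all pairwise distances are undefined")
  structure(list(ids = ids, d = d, P = P, Q = Q, usable_sites = ns,
                 undefined_pairs = undefined_pairs, gap_mode = gap_mode),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("dist_matrix (K2P):", length(x$ids), "ids,",
      nrow(x$undefined_pairs), "undefined pair(s), gap_mode =",
      x$gap_mode, "\n")
  invisible(x)
}

#' Build a dist_matrix from a plain symmetric matrix
#'
#' Convenience constructor used for toy examples and for feeding
#' externally computed distances into the delimitation functions.
#'
#' @param m Symmetric numeric matrix with dimnames (NA = undefined pair).
#' @return A `dist_matrix`.
#' @export
as_dist_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(m)))
  dimnames(m) <- list(ids, ids)
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-12) stop("matrix not symmetric")
  diag(m) <- 0
  undef <- is.na(m)
  und <- which(undef & upper.tri(undef), arr.ind = TRUE)
  structure(list(ids = ids, d = m, P = NULL, Q = NULL,
                 usable_sites = NULL,
                 undefined_pairs = cbind(ids[und[, 1]], ids[und[, 2]]),
                 gap_mode = "external"),
            class = "dist_matrix")
}

#' Extract the numeric distance matrix
#' @param dm A `dist_matrix`.
#' @return Symmetric numeric matrix (NA for undefined pairs).
#' @export
dist_values <- function(dm) dm$d

#' Export a distance matrix as square TSV
#'
#' Ids form the first row and column; decimal points are always `.`
#' regardless of locale.
#'
#' @param dm A `dist_matrix`.
#' @param path Output path.
#' @param percent Render distances as percentages with 2 decimals
#'   (report style) instead of raw proportions.
#' @return `path`, invisibly.
#' @export
write_dist_tsv <- function(dm, path, percent = FALSE) {
  m <- dm$d
  if (percent) m <- round(100 * m, 2)
  df <- data.frame(seq_id = dm$ids, m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mutational step count between two encoded haplotypes
#'
#' Hamming distance over a recoded [character_matrix()]: every substitution
#' column and every recoded indel block or structural mutation contributes
#' at most one step, so a multi-base indel counts once, matching the
#' equal-weight single-step treatment used for haplotype networks.
#' Characters where either sequence has an inapplicable state (NA) are
#' skipped.
#'
#' @param cm A [character_matrix()].
#' @param id_a,id_b Sequence ids present in the encoding.
#' @return Integer number of steps.
#' @export
step_count_pair <- function(cm, id_a, id_b) {
  stopifnot(inherits(cm, "character_matrix"))
  if (!id_a %in% cm$ids) stop("id not in encoding: ", id_a)
  if (!id_b %in% cm$ids) stop("id not in encoding: ", id_b)
  sa <- cm$states[id_a, ]
  sb <- cm$states[id_b, ]
  ok <- !is.na(sa) & !is.na(sb)
  sum(sa[ok] != sb[ok])
}
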