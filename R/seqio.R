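#' @keywords internal
"_PACKAGE"

IUPAC_OK <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N", "-")

#' Construct an aligned sequence set
#'
#' An `aligned_set` holds equal-length (aligned) marker sequences together
#' with per-sequence specimen metadata. All distance, delimitation, tree and
#' network computations in the package consume this container. Alignment is
#' an input contract: sequences of unequal length are refused rather than
#' aligned silently.
#'
#' @param seqs Named character vector of aligned sequences (names are
#'   sequence ids; the first whitespace-delimited FASTA header token).
#' @param marker Marker label, typically `"COI"` or `"ITS2"`.
#' @param meta Optional metadata `data.frame` as returned by
#'   [read_metadata()]; merged by `seq_id`, with warnings and immature
#'   defaults for ids absent from it.
#' @return An object of class `aligned_set`: a list with elements `ids`,
#'   `mat` (character matrix, one row per sequence), `length` (alignment
#'   columns), `marker` and `meta`.
#' @export
aligned_set <- function(seqs, marker = "other", meta = NULL) {
  if (length(seqs) == 0) {
    mat <- matrix(character(0), nrow = 0, ncol = 0)
    obj <- structure(list(ids = character(0), mat = mat, length = 0L,
                          marker = marker, meta = empty_metadata(character(0))),
                     class = "aligned_set")
    return(obj)
  }
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("every sequence must be named by a non-empty id")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    stop("unaligned input: sequence lengths differ (",
         paste(range(lens), collapse = "-"),
         "); align the sequences before loading them")
  }
  if (lens[1] == 0L) stop("sequences must be non-empty")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- ids
  bad <- !(mat %in% IUPAC_OK)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow = nrow(mat)), arr.ind = TRUE)[1, ]
    stop("illegal character '", mat[idx[1], idx[2]], "' in record '",
         ids[idx[1]], "' at column ", idx[2])
  }
  structure(list(ids = ids, mat = mat, length = ncol(mat),
                 marker = marker, meta = resolve_metadata(ids, meta)),
            class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat("aligned_set:", length(x$ids), x$marker, "sequences x",
      x$length, "columns\n")
  invisible(x)
}

empty_metadata <- function(ids) {
  n <- length(ids)
  data.frame(seq_id = ids,
             specimen_id = ids,
             clone_id = rep(NA_character_, n),
             morphotaxon = rep(NA_character_, n),
             maturity = rep("immature", n),
             stringsAsFactors = FALSE)
}

resolve_metadata <- function(ids, meta) {
  out <- empty_metadata(ids)
  if (is.null(meta)) return(out)
  miss <- setdiff(ids, meta$seq_id)
  if (length(miss) > 0) {
    warning("no metadata for ", length(miss), " sequence id(s) (",
            paste(utils::head(miss, 3), collapse = ", "),
            if (length(miss) > 3) ", ..." else "",
            "); defaults applied (immature, unassigned)")
  }
  hit <- match(ids, meta$seq_id)
  extra <- setdiff(names(meta), c("seq_id", names(out)))
  for (col in c("specimen_id", "clone_id", "morphotaxon", "maturity",
                extra)) {
    if (col %in% names(meta)) {
      if (!col %in% names(out)) out[[col]] <- NA_character_
      vals <- as.character(meta[[col]][hit])
      keep <- !is.na(hit) & !is.na(vals) & vals != ""
      out[[col]][keep] <- vals[keep]
    }
  }
  out
}

#' Read an aligned multi-FASTA file
#'
#' Headers are parsed so that the sequence id is the first
#' whitespace-delimited token; the remainder of the header is kept as a
#' free-text description. Residues are uppercased on ingest and validated
#' against the nucleotide IUPAC alphabet (plus `-` for alignment gaps).
#' Unequal sequence lengths raise an unaligned-input error.
#'
#' @param path FASTA file path.
#' @param marker Marker label attached to the set.
#' @param meta Optional metadata `data.frame` (see [read_metadata()]).
#' @return An [aligned_set()].
#' @export
read_fasta <- function(path, marker = "other", meta = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) {
    warning("empty FASTA file: ", path)
    return(aligned_set(character(0), marker = marker))
  }
  seqs <- as.character(ss)
  headers <- names(ss)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[`, character(1), 1L)
  names(seqs) <- ids
  aligned_set(seqs, marker = marker, meta = meta)
}

#' Write an aligned set to FASTA
#'
#' Round-trips exactly: `read_fasta(write_fasta(x))` reproduces ids,
#' residues (including gap columns) and record order.
#'
#' @param aligned An [aligned_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aligned, path) {
  stopifnot(inherits(aligned, "aligned_set"))
  if (length(aligned$ids) == 0) {
    warning("writing empty FASTA file")
    cat("", file = path)
    return(invisible(path))
  }
  seqs <- apply(aligned$mat, 1, paste, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- aligned$ids
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Read the specimen metadata sidecar table
#'
#' Tab-separated, one row per sequence, with a header row. Recognised
#' columns: `seq_id` (required), `specimen_id`, `clone_id`, `morphotaxon`,
#' `maturity`. Missing morphotaxon labels are treated downstream as
#' unassigned immatures; clone ids tie multiple cloned copies (e.g. nuclear
#' ITS2 clones) back to one specimen.
#'
#' @param path TSV path.
#' @return A `data.frame` keyed by `seq_id`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  if (!"seq_id" %in% names(meta)) stop("metadata must have a seq_id column")
  if (anyDuplicated(meta$seq_id)) {
    stop("duplicate seq_id rows in metadata: ",
         paste(unique(meta$seq_id[duplicated(meta$seq_id)]), collapse = ", "))
  }
  if (!"maturity" %in% names(meta)) meta$maturity <- "identified"
  meta$maturity[is.na(meta$maturity) | meta$maturity == ""] <- "immature"
  meta
}

#' Write a metadata table
#' @param meta Metadata `data.frame`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Subset an aligned set by sequence id
#' @param aligned An [aligned_set()].
#' @param ids Sequence ids to keep (order preserved as given).
#' @return An [aligned_set()] restricted to `ids`.
#' @export
subset_aligned <- function(aligned, ids) {
  stopifnot(all(ids %in% aligned$ids))
  seqs <- apply(aligned$mat[ids, , drop = FALSE], 1, paste, collapse = "")
  names(seqs) <- ids
  aligned_set(seqs, marker = aligned$marker, meta = aligned$meta)
}
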