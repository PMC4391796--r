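#' Map specimens to the lineage(s) of their sequences
#'
#' Sequences belong to specimens (possibly via multiple cloned copies for
#' nuclear markers). A specimen whose clones fall into two or more
#' lineages is flagged polymorphic — evidence of intra-individual copy
#' variation — rather than force-assigned to one lineage.
#'
#' @param partition A `lineage_partition`.
#' @param meta Metadata `data.frame` resolving every partitioned `seq_id`
#'   to a `specimen_id`.
#' @return `data.frame` with `specimen_id`, `lineages` (comma-joined),
#'   `n_lineages`, `polymorphic`.
#' @export
specimen_lineage <- function(partition, meta) {
  ids <- names(partition$assignment)
  hit <- match(ids, meta$seq_id)
  if (anyNA(hit)) stop("unknown seq_id in metadata lookup: ",
                       ids[which(is.na(hit))[1]])
  spec <- meta$specimen_id[hit]
  by_spec <- split(unname(partition$assignment), spec)
  lin_sets <- lapply(by_spec, function(x) sort(unique(x)))
  data.frame(specimen_id = names(lin_sets),
             lineages = vapply(lin_sets, paste, character(1),
                               collapse = ","),
             n_lineages = vapply(lin_sets, length, integer(1)),
             polymorphic = vapply(lin_sets, length, integer(1)) > 1,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare two marker partitions over shared specimens
#'
#' Maps lineages of partition A (e.g. mitochondrial) onto lineages of
#' partition B (e.g. nuclear) through the specimens sequenced for both
#' markers, and lists the discrepancies:
#' * `merge` — one B-lineage contains specimens from two or more
#'   A-lineages (B fails to separate what A separates);
#' * `split` — the inverse;
#' * `tangled` — specimens whose B-marker copies fall into several
#'   B-lineages (intra-individual polymorphism blurring the comparison).
#'
#' @param pA,pB `lineage_partition` objects for the two markers.
#' @param metaA,metaB Metadata resolving each marker's sequences to
#'   specimens.
#' @return An object of class `concordance_report`: list with
#'   `shared_specimens`, `a_to_b` / `b_to_a` mappings,
#'   `discrepancies` (`data.frame`: `type`, `lineages_a`, `lineages_b`,
#'   `specimens`), `n_discrepancies` and `n_concordant`.
#' @export
compare_partitions <- function(pA, pB, metaA, metaB = metaA) {
  slA <- specimen_lineage(pA, metaA)
  slB <- specimen_lineage(pB, metaB)
  shared <- intersect(slA$specimen_id, slB$specimen_id)
  if (length(shared) == 0) {
    warning("no shared specimens between the two partitions")
    return(structure(list(shared_specimens = character(0),
                          a_to_b = list(), b_to_a = list(),
                          discrepancies = empty_discrepancies(),
                          n_discrepancies = 0L, n_concordant = 0L),
                     class = "concordance_report"))
  }
  sA <- slA[match(shared, slA$specimen_id), ]
  sB <- slB[match(shared, slB$specimen_id), ]
  la <- strsplit(sA$lineages, ","); names(la) <- shared
  lb <- strsplit(sB$lineages, ","); names(lb) <- shared

  a_labs <- sort(unique(unlist(la)))
  b_labs <- sort(unique(unlist(lb)))
  a_to_b <- lapply(stats::setNames(a_labs, a_labs), function(al) {
    sort(unique(unlist(lb[vapply(la, function(x) al %in% x, logical(1))])))
  })
  b_to_a <- lapply(stats::setNames(b_labs, b_labs), function(bl) {
    sort(unique(unlist(la[vapply(lb, function(x) bl %in% x, logical(1))])))
  })

  disc <- empty_discrepancies()
  tangled_specs <- shared[sB$polymorphic[match(shared, sB$specimen_id)]]
  # tangled cases first: B-lineages linked only through polymorphic
  # specimens are copy-polymorphism evidence, not clean merges
  tangled_b <- sort(unique(unlist(lb[tangled_specs])))
  if (length(tangled_specs)) {
    disc <- rbind(disc, data.frame(
      type = "tangled",
      lineages_a = paste(sort(unique(unlist(la[tangled_specs]))),
                         collapse = ","),
      lineages_b = paste(tangled_b, collapse = ","),
      specimens = paste(sort(tangled_specs), collapse = ","),
      stringsAsFactors = FALSE))
  }
  for (bl in b_labs) {
    src <- b_to_a[[bl]]
    if (length(src) >= 2 && !(bl %in% tangled_b)) {
      specs <- shared[vapply(lb, function(x) bl %in% x, logical(1))]
      disc <- rbind(disc, data.frame(
        type = "merge", lineages_a = paste(src, collapse = ","),
        lineages_b = bl, specimens = paste(sort(specs), collapse = ","),
        stringsAsFactors = FALSE))
    }
  }
  tangled_a <- sort(unique(unlist(la[slA$specimen_id[slA$polymorphic]])))
  for (al in a_labs) {
    tgt <- a_to_b[[al]]
    if (length(tgt) >= 2 && !(al %in% tangled_a)) {
      # a split of A by B; skip when driven purely by B-copy polymorphism
      specs <- shared[vapply(la, function(x) al %in% x, logical(1))]
      pure_poly <- all(specs %in% tangled_specs)
      if (!pure_poly) {
        disc <- rbind(disc, data.frame(
          type = "split", lineages_a = al,
          lineages_b = paste(tgt, collapse = ","),
          specimens = paste(sort(specs), collapse = ","),
          stringsAsFactors = FALSE))
      }
    }
  }
  n_conc <- sum(vapply(a_to_b, length, integer(1)) == 1 &
                  !(a_labs %in% unlist(strsplit(disc$lineages_a, ","))))
  structure(list(shared_specimens = shared,
                 a_to_b = a_to_b, b_to_a = b_to_a,
                 discrepancies = disc,
                 n_discrepancies = nrow(disc),
                 n_concordant = n_conc),
            class = "concordance_report")
}

empty_discrepancies <- function() {
  data.frame(type = character(0), lineages_a = character(0),
             lineages_b = character(0), specimens = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("concordance_report:", length(x$shared_specimens),
      "shared specimens,", x$n_discrepancies, "discrepancy(ies)\n")
  if (x$n_discrepancies > 0) print(x$discrepancies)
  invisible(x)
}

#' Morphological versus genetic diversity summary
#'
#' Counts, per higher group (family/subfamily) and in total, the number of
#' morphologically recognisable taxa against the number of genetic
#' lineages. Morphotaxon counting: every distinct morphotaxon label counts
#' once, including explicit morpho-group labels carried by unidentifiable
#' immatures (e.g. "with/without hair setae" groups); immatures with no
#' label at all are pooled into one indeterminate taxon per higher group.
#' A morphotaxon spanning several lineages is a cryptic complex.
#'
#' @param partition A `lineage_partition`.
#' @param meta Metadata with `specimen_id`, `morphotaxon`, `maturity` and
#'   optionally a `group` column (higher group); missing `group` yields a
#'   single overall row.
#' @return List with `by_group` (`data.frame`: `group`, `n_morphotaxa`,
#'   `n_lineages`), `totals`, and `cryptic_complexes` (`data.frame`:
#'   `morphotaxon`, `n_lineages`).
#' @export
diversity_summary <- function(partition, meta) {
  ids <- names(partition$assignment)
  hit <- match(ids, meta$seq_id)
  if (anyNA(hit)) stop("metadata missing for seq_id: ",
                       ids[which(is.na(hit))[1]])
  grp <- if ("group" %in% names(meta)) meta$group[hit]
         else rep("all", length(ids))
  grp[is.na(grp) | grp == ""] <- "unassigned"
  taxon <- meta$morphotaxon[hit]
  none <- is.na(taxon) | taxon == ""
  taxon[none] <- paste0(grp[none], "_indet")
  lin <- unname(partition$assignment)

  by_group <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    sel <- grp == g
    data.frame(group = g,
               n_morphotaxa = length(unique(taxon[sel])),
               n_lineages = length(unique(lin[sel])),
               stringsAsFactors = FALSE)
  }))
  # lineages spanning two groups (should not happen with clean metadata)
  # are counted in each group but once in the totals
  totals <- data.frame(group = "total",
                       n_morphotaxa = length(unique(taxon)),
                       n_lineages = length(unique(lin)),
                       stringsAsFactors = FALSE)
  tab <- table(taxon = taxon, lineage = lin)
  n_lin_per_taxon <- rowSums(tab > 0)
  cc <- n_lin_per_taxon[n_lin_per_taxon >= 2]
  cryptic <- data.frame(morphotaxon = names(cc),
                        n_lineages = as.integer(cc),
                        stringsAsFactors = FALSE, row.names = NULL)
  list(by_group = by_group, totals = totals,
       cryptic_complexes = cryptic[order(cryptic$morphotaxon), ,
                                   drop = FALSE])
}

#' Write the diversity summary as TSV
#' @param summary Output of [diversity_summary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diversity_tsv <- function(summary, path) {
  utils::write.table(rbind(summary$by_group, summary$totals), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
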