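#' Configuration for the two-marker lineage simulator
#'
#' Defines a dataset of `n_lineages` discrete lineages with a barcode gap
#' by construction: lineage ancestors diverge from a common root by
#' `inter_divergence` (K2P target, default 12–25%), members diverge from
#' their ancestor by `intra_divergence` (default 0–2%), substitutions are
#' transition-biased (`kappa`). A second, slower marker (divergence scaled
#' by `marker2_rate_scale`) carries lineage-level multi-base deletion
#' blocks and is sequenced as multiple clones per specimen with small
#' intra-individual copy noise — the structure of a nuclear ribosomal
#' spacer complementing a mitochondrial barcode.
#'
#' @param n_lineages Number of true lineages.
#' @param members_per_lineage Integer range (or set) member counts are
#'   drawn from, per lineage.
#' @param lineage_sizes Optional explicit member count per lineage
#'   (overrides `members_per_lineage`).
#' @param seq_length Marker-1 alignment length (default 600, the scale of
#'   a COI barcode fragment).
#' @param inter_divergence Range of root-to-ancestor K2P targets.
#' @param intra_divergence Range of ancestor-to-member K2P targets.
#' @param kappa Transition/transversion rate ratio (default 4).
#' @param marker2_rate_scale Marker-2 divergence relative to marker 1
#'   (default 0.25).
#' @param marker2_length Marker-2 alignment length (default 350, a
#'   typical spacer amplicon).
#' @param marker2_indel_rate Expected number of deletion blocks per
#'   lineage on marker 2 (Poisson mean, default 0.5).
#' @param indel_block_range Deletion block lengths (default 2–8 bp).
#' @param clones_per_specimen Range of marker-2 clones per specimen.
#' @param clone_noise Range of K2P copy-noise targets per clone
#'   (default 0–0.5%).
#' @param planted_sublineages Named numeric vector: lineage index (as
#'   character) -> within-lineage split divergence; members are split
#'   between two sub-ancestors that far apart (used via [degrade_gap()]).
#' @param marker2_merged_pairs List of `c(i, j)` lineage index pairs whose
#'   marker-2 sequences are made identical (a marker discordance of type
#'   merge).
#' @param marker2_tangled_pairs List of `c(i, j)` pairs whose specimens
#'   receive marker-2 clones from both lineages' copy classes
#'   (intra-individual polymorphism; discordance of type tangled).
#' @param morphotaxon_of Optional character vector, one label per lineage,
#'   to emulate cryptic complexes (several lineages sharing a label) and
#'   immature morpho-groups; default gives each lineage its own label.
#' @param group_of Optional character vector, one higher-group (family)
#'   label per lineage.
#' @param seed Mandatory integer seed; fixed seed gives byte-identical
#'   outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_lineages = 8,
                       members_per_lineage = 1:6,
                       lineage_sizes = NULL,
                       seq_length = 600,
                       inter_divergence = c(0.12, 0.25),
                       intra_divergence = c(0, 0.02),
                       kappa = 4,
                       marker2_rate_scale = 0.25,
                       marker2_length = 350,
                       marker2_indel_rate = 0.5,
                       indel_block_range = 2:8,
                       clones_per_specimen = 1:4,
                       clone_noise = c(0, 0.005),
                       planted_sublineages = NULL,
                       marker2_merged_pairs = NULL,
                       marker2_tangled_pairs = NULL,
                       morphotaxon_of = NULL,
                       group_of = NULL,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_lineages >= 1, seq_length >= 50, marker2_length >= 50,
            kappa > 0, marker2_rate_scale > 0, marker2_rate_scale < 1)
  if (max(intra_divergence) >= min(inter_divergence)) {
    stop("intra_divergence must lie entirely below inter_divergence ",
         "(the simulated barcode gap would vanish)")
  }
  if (!is.null(lineage_sizes)) stopifnot(length(lineage_sizes) == n_lineages)
  if (!is.null(morphotaxon_of)) stopifnot(length(morphotaxon_of) == n_lineages)
  if (!is.null(group_of)) stopifnot(length(group_of) == n_lineages)
  structure(as.list(environment()), class = "sim_config")
}

# solve K2P for the transition/transversion proportions giving target d,
# keeping the realized P/Q ratio at kappa/2 (two transversion channels)
k2p_invert <- function(d, kappa) {
  if (d <= 0) return(c(P = 0, Q = 0))
  r <- kappa / 2
  f <- function(q) {
    -0.5 * log(1 - 2 * r * q - q) - 0.25 * log(1 - 2 * q) - d
  }
  qmax <- 1 / (2 * r + 1) - 1e-9
  q <- stats::uniroot(f, c(1e-12, qmax), tol = 1e-12)$root
  c(P = r * q, Q = q)
}

TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))

# place round(P*L) transitions and round(Q*L) transversions at distinct
# random sites (expected-count inversion of the K2P formula)
evolve_seq <- function(seq, d, kappa) {
  if (d <= 0) return(seq)
  L <- length(seq)
  pq <- k2p_invert(d, kappa)
  n_ts <- round(pq["P"] * L)
  n_tv <- round(pq["Q"] * L)
  n_mut <- n_ts + n_tv
  if (n_mut == 0) return(seq)
  sites <- sample.int(L, min(n_mut, L))
  ts_sites <- sites[seq_len(min(n_ts, length(sites)))]
  tv_sites <- setdiff(sites, ts_sites)
  seq[ts_sites] <- TS_PARTNER[seq[ts_sites]]
  for (s in tv_sites) seq[s] <- sample(TV_PARTNERS[[seq[s]]], 1)
  seq
}

runif_range <- function(n, range) {
  if (length(range) == 1) rep(range, n)
  else stats::runif(n, range[1], range[2])
}

#' Simulate a two-marker dataset with known lineage truth
#'
#' Draws a uniform random root sequence, evolves one ancestor per lineage
#' to an `inter_divergence` K2P target, evolves each member (one specimen
#' per member) to an `intra_divergence` target, and derives a slower
#' second marker with lineage-level deletion blocks (realised as aligned
#' gap columns) and per-specimen clone copies carrying low-level copy
#' noise. Planted sublineages, marker-2 merges and clone tangles are
#' applied when configured. Identical configurations (including the seed)
#' yield byte-identical outputs.
#'
#' @param cfg A [sim_config()].
#' @return List with `marker1`, `marker2` ([aligned_set()]s), `truth`
#'   (a `lineage_partition` over marker-1 sequences), `truth2` (the
#'   marker-2 truth, clones included), `meta` (metadata `data.frame`
#'   covering both markers) and `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  K <- cfg$n_lineages
  sizes <- if (!is.null(cfg$lineage_sizes)) as.integer(cfg$lineage_sizes)
           else sample(cfg$members_per_lineage, K, replace = TRUE)
  morpho <- if (!is.null(cfg$morphotaxon_of)) cfg$morphotaxon_of
            else sprintf("Morphospecies_%02d", seq_len(K))
  group <- if (!is.null(cfg$group_of)) cfg$group_of else rep("all", K)

  acgt <- c("A", "C", "G", "T")
  root1 <- sample(acgt, cfg$seq_length, replace = TRUE)
  root2 <- sample(acgt, cfg$marker2_length, replace = TRUE)

  inter_targets <- runif_range(K, cfg$inter_divergence)
  anc1 <- lapply(inter_targets, function(d) evolve_seq(root1, d, cfg$kappa))
  anc2 <- lapply(inter_targets * cfg$marker2_rate_scale,
                 function(d) evolve_seq(root2, d, cfg$kappa))

  # marker-2 lineage-level deletion blocks (shared by members and clones)
  del_iv <- vector("list", K)
  for (k in seq_len(K)) {
    nb <- stats::rpois(1, cfg$marker2_indel_rate)
    if (nb > 0) {
      iv <- matrix(0L, nb, 2)
      for (b in seq_len(nb)) {
        len <- sample(cfg$indel_block_range, 1)
        start <- sample.int(cfg$marker2_length - len + 1L, 1)
        iv[b, ] <- c(start, start + len - 1L)
      }
      del_iv[[k]] <- iv
    }
  }

  if (!is.null(cfg$marker2_merged_pairs)) {
    for (pr in cfg$marker2_merged_pairs) {
      anc2[[pr[2]]] <- anc2[[pr[1]]]
      del_iv[pr[2]] <- del_iv[pr[1]]   # single bracket: NULL must copy
    }
  }
  merged_lineages <- unique(unlist(cfg$marker2_merged_pairs))
  tangled_lineages <- unique(unlist(cfg$marker2_tangled_pairs))
  tangle_partner <- integer(0)
  for (pr in cfg$marker2_tangled_pairs) {
    tangle_partner[pr[1]] <- pr[2]
    tangle_partner[pr[2]] <- pr[1]
  }

  planted <- cfg$planted_sublineages
  sub_anc1 <- lapply(seq_len(K), function(k) {
    key <- as.character(k)
    if (!is.null(planted) && key %in% names(planted)) {
      evolve_seq(anc1[[k]], planted[[key]], cfg$kappa)
    } else NULL
  })

  seqs1 <- list(); seqs2 <- list()
  meta_rows <- list()
  truth1 <- character(0); truth2 <- character(0)
  spec_counter <- 0L
  for (k in seq_len(K)) {
    lab <- sprintf("T%02d", k)
    for (mmb in seq_len(sizes[k])) {
      spec_counter <- spec_counter + 1L
      sp <- sprintf("sp%03d", spec_counter)
      intra <- runif_range(1, cfg$intra_divergence)
      # planted sublineage: odd members from the lineage ancestor, even
      # members from the shifted sub-ancestor; sublineages are tight
      # haplotype clusters (copy-noise level spread), so the realized
      # between-sublineage divergence stays at the planted value instead
      # of being inflated by ordinary member noise
      planted_here <- !is.null(sub_anc1[[k]])
      if (planted_here) intra <- runif_range(1, cfg$clone_noise)
      base1 <- if (planted_here && mmb %% 2 == 0)
        sub_anc1[[k]] else anc1[[k]]
      s1 <- evolve_seq(base1, intra, cfg$kappa)
      id1 <- paste0(sp, "_m1")
      seqs1[[id1]] <- paste(s1, collapse = "")
      truth1[id1] <- lab
      meta_rows[[id1]] <- data.frame(
        seq_id = id1, specimen_id = sp, clone_id = NA_character_,
        marker = "marker1", morphotaxon = morpho[k], group = group[k],
        maturity = if (is.na(morpho[k]) || morpho[k] == "") "immature"
                   else "identified",
        stringsAsFactors = FALSE)

      m2_intra <- if (k %in% merged_lineages) 0 else
        intra * cfg$marker2_rate_scale
      s2_body <- evolve_seq(anc2[[k]], m2_intra, cfg$kappa)
      n_cl <- sample(cfg$clones_per_specimen, 1)
      tangled <- k %in% tangled_lineages
      if (tangled) n_cl <- max(n_cl, 2L)
      for (cl in seq_len(n_cl)) {
        src_k <- k
        body <- s2_body
        if (tangled && cl %% 2 == 0) {
          # alternate clones come from the partner lineage's copy class
          src_k <- tangle_partner[k]
          body <- evolve_seq(anc2[[src_k]],
                             m2_intra, cfg$kappa)
        }
        cn <- if (k %in% merged_lineages) 0 else
          runif_range(1, cfg$clone_noise)
        s2 <- evolve_seq(body, cn, cfg$kappa)
        if (!is.null(del_iv[[src_k]])) {
          for (b in seq_len(nrow(del_iv[[src_k]]))) {
            s2[del_iv[[src_k]][b, 1]:del_iv[[src_k]][b, 2]] <- "-"
          }
        }
        id2 <- paste0(sp, "_c", cl)
        seqs2[[id2]] <- paste(s2, collapse = "")
        truth2[id2] <- sprintf("T%02d", src_k)
        meta_rows[[id2]] <- data.frame(
          seq_id = id2, specimen_id = sp,
          clone_id = if (n_cl > 1) paste0("c", cl) else NA_character_,
          marker = "marker2", morphotaxon = morpho[k], group = group[k],
          maturity = if (is.na(morpho[k]) || morpho[k] == "") "immature"
                     else "identified",
          stringsAsFactors = FALSE)
      }
    }
  }
  meta <- do.call(rbind, c(meta_rows, make.row.names = FALSE))
  marker1 <- aligned_set(unlist(seqs1), marker = "marker1", meta = meta)
  marker2 <- aligned_set(unlist(seqs2), marker = "marker2", meta = meta)
  list(marker1 = marker1, marker2 = marker2,
       truth = as_lineage_partition(truth1),
       truth2 = as_lineage_partition(truth2),
       meta = meta, config = cfg)
}

#' Degrade the barcode gap by planting sublineages
#'
#' Returns a configuration in which chosen lineages contain two
#' sub-ancestors a known divergence apart (default 8%), so that a 10%
#' partition keeps each lineage whole while a 5% partition splits it —
#' the behaviour of cryptic sublineages sitting inside the barcode gap.
#'
#' @param cfg A [sim_config()].
#' @param lineages Integer indices of lineages to plant sublineages in.
#' @param divergences Sub-ancestor divergence per planted lineage
#'   (recycled; default 0.08).
#' @return A modified `sim_config`.
#' @export
degrade_gap <- function(cfg, lineages = 1L, divergences = 0.08) {
  stopifnot(inherits(cfg, "sim_config"), all(lineages >= 1),
            all(lineages <= cfg$n_lineages))
  divergences <- rep_len(divergences, length(lineages))
  planted <- as.list(divergences)
  names(planted) <- as.character(lineages)
  cfg$planted_sublineages <- planted
  cfg
}

#' Write a simulated dataset to disk
#'
#' Emits the exact input formats the readers consume: two aligned FASTA
#' files, the metadata TSV, and a truth TSV (`seq_id`, `true_lineage`).
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(marker1 = file.path(dir, "marker1.fasta"),
             marker2 = file.path(dir, "marker2.fasta"),
             meta = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_fasta(sim$marker1, paths["marker1"])
  write_fasta(sim$marker2, paths["marker2"])
  write_metadata(sim$meta, paths["meta"])
  truth_df <- data.frame(
    seq_id = c(names(sim$truth$assignment), names(sim$truth2$assignment)),
    true_lineage = c(unname(sim$truth$assignment),
                     unname(sim$truth2$assignment)),
    stringsAsFactors = FALSE)
  utils::write.table(truth_df, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
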