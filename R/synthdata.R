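# Synthetic multi-omics cohorts with the statistical structure the framework
# assumes: log-normal compositional abundances, blocks of highly correlated
# spectral buckets (intramolecular resonances), planted inter-omics monotone
# correlations (consortia) and arm/timepoint effects. Built on a Gaussian
# latent-factor model with exponential marginals: Spearman correlation is
# invariant to the monotone marginal transform, so planted rank correlations
# are exact in expectation.

#' Configuration for a simulated cohort
#'
#' Defaults emulate a two-arm, two-sex nutritional intervention of realistic
#' size (22 subjects per sex-by-arm cell, close to the ~90 completers of a
#' typical trial sub-study) with two microbial-metabolic consortia sharing
#' one taxon, twelve five-bucket NMR "molecules" and an intervention effect
#' on two molecule blocks at endpoint.
#'
#' @param n_subjects_per_cell Subjects per sex x arm cell (each sampled at T0
#'   and Te).
#' @param n_taxa,n_vocs,n_buckets Feature counts per omics block.
#' @param consortia List of consortium definitions, each a list with integer
#'   indices `taxa`, `vocs`, `blocks` (bucket-block indices whose molecule
#'   latent follows the consortium factor) and optionally `arm` /
#'   `timepoint` restricting where the consortium is active. A feature listed
#'   in exactly two unrestricted consortia becomes a bridge feature.
#' @param molecule_blocks List of integer vectors partitioning (a subset of)
#'   bucket indices into molecules; remaining buckets are independent.
#' @param rho_plant Latent within-consortium correlation, in (0, 1)
#'   (default 0.95).
#' @param rho_bridge Latent correlation between a shared feature and the
#'   members of each consortium it belongs to (default 0.845; bounded above by
#'   `sqrt(rho_plant * (1 + factor_cor) / 2)`).
#' @param factor_cor Correlation between the factors of consortia that share
#'   a feature (default 0.52).
#' @param block_cor Intra-molecule bucket correlation (default 0.95).
#' @param arm_effect_blocks Molecule blocks shifted in arm A at Te
#'   (default `c(3, 4)`).
#' @param arm_effect_size Latent shift applied there (default 1, in latent SD
#'   units).
#' @param noise_sd Extra measurement noise on the log scale (default 0.02).
#' @param seed Integer seed controlling the whole draw.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects_per_cell = 22,
                       n_taxa = 30, n_vocs = 12, n_buckets = 60,
                       consortia = NULL, molecule_blocks = NULL,
                       rho_plant = 0.95, rho_bridge = 0.845,
                       factor_cor = 0.52, block_cor = 0.95,
                       arm_effect_blocks = c(3, 4), arm_effect_size = 1,
                       noise_sd = 0.02, seed = 1) {
  if (is.null(consortia)) {
    consortia <- list(
      list(taxa = 1:6, vocs = 1:2, blocks = integer(0)),
      list(taxa = 6:11, vocs = 3:4, blocks = integer(0)))
  }
  if (is.null(molecule_blocks)) {
    n_blocks <- n_buckets %/% 5
    molecule_blocks <- split(seq_len(n_blocks * 5),
                             rep(seq_len(n_blocks), each = 5))
    molecule_blocks <- unname(molecule_blocks)
  }
  stopifnot(rho_plant > 0, rho_plant < 1, block_cor > 0, block_cor <= 1,
            factor_cor >= 0, factor_cor < 1, noise_sd >= 0,
            n_subjects_per_cell >= 1)
  if (length(molecule_blocks) > 0 &&
      anyDuplicated(unlist(molecule_blocks))) {
    stop("molecule blocks must be disjoint", call. = FALSE)
  }
  for (cs in consortia) {
    if (any(cs$taxa > n_taxa) || any(cs$vocs > n_vocs) ||
        any(cs$blocks > length(molecule_blocks))) {
      stop("consortium index out of range", call. = FALSE)
    }
  }
  if (any(arm_effect_blocks > length(molecule_blocks))) {
    stop("arm-effect block index out of range", call. = FALSE)
  }
  # features can only be shared between unrestricted consortia
  if (length(consortia) >= 2) {
    for (i in seq_len(length(consortia) - 1)) {
      for (j in (i + 1):length(consortia)) {
        shared <- length(intersect(consortia[[i]]$taxa, consortia[[j]]$taxa)) +
          length(intersect(consortia[[i]]$vocs, consortia[[j]]$vocs))
        scoped <- !is.null(consortia[[i]]$arm) || !is.null(consortia[[i]]$timepoint) ||
          !is.null(consortia[[j]]$arm) || !is.null(consortia[[j]]$timepoint)
        if (shared > 0 && scoped) {
          stop("arm/timepoint-restricted consortia cannot share features",
               call. = FALSE)
        }
      }
    }
  }
  structure(list(n_subjects_per_cell = n_subjects_per_cell, n_taxa = n_taxa,
                 n_vocs = n_vocs, n_buckets = n_buckets,
                 consortia = consortia, molecule_blocks = molecule_blocks,
                 rho_plant = rho_plant, rho_bridge = rho_bridge,
                 factor_cor = factor_cor, block_cor = block_cor,
                 arm_effect_blocks = arm_effect_blocks,
                 arm_effect_size = arm_effect_size,
                 noise_sd = noise_sd, seed = seed),
            class = "sim_config")
}

#' Simulate a two-timepoint multi-omics cohort
#'
#' Draws, per timepoint, latent Gaussian factors per consortium (factors of
#' consortia sharing a feature are correlated by `factor_cor`), loads members
#' with `sqrt(rho_plant)`, gives a shared feature a symmetric loading on both
#' of its factors calibrated so its correlation to either consortium's
#' members is `rho_bridge`, and maps latents to observations through
#' `exp(mu + sigma * z)`. Taxa and VOC blocks are renormalised to sum to
#' 100% per sample (compositional; each block includes one dominant,
#' low-variance feature so the renormalisation denominator stays stable),
#' while NMR buckets stay positive intensities. Arm A samples at Te receive
#' the configured latent shift on the arm-effect molecule blocks. The draw is
#' fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list: `t0` and `te` (merged `feature_table`s of taxa RA%, VOC
#'   RA% and bucket intensities), `design` ([sample_design()] over all
#'   samples), and `truth` (planted consortium feature ids, bridge ids,
#'   molecule-block bucket ids, arm-affected bucket ids).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  rs <- local_rng(cfg$seed)
  on.exit(restore_rng(rs))

  cells <- expand.grid(sex = c("F", "M"), arm = c("A", "P"),
                       stringsAsFactors = FALSE)
  subj <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(subject_id = sprintf("%s%s%03d", cells$sex[i], cells$arm[i],
                                    seq_len(cfg$n_subjects_per_cell)),
               sex = cells$sex[i], arm = cells$arm[i],
               stringsAsFactors = FALSE)
  }))
  n_subj <- nrow(subj)

  taxa_ids <- sprintf("taxon_%02d", seq_len(cfg$n_taxa))
  voc_ids <- sprintf("voc_%02d", seq_len(cfg$n_vocs))
  bucket_ids <- sprintf("bucket_%03d", seq_len(cfg$n_buckets))

  feat_of <- function(cs) {
    c(taxa_ids[cs$taxa], voc_ids[cs$vocs],
      if (length(cs$blocks) > 0) {
        bucket_ids[unlist(cfg$molecule_blocks[cs$blocks])]
      })
  }
  consortium_feats <- lapply(cfg$consortia, feat_of)
  memb_count <- table(unlist(consortium_feats))
  if (any(memb_count > 2)) {
    stop("a feature may belong to at most 2 consortia", call. = FALSE)
  }
  bridge_ids <- names(memb_count)[memb_count == 2]

  nc <- length(cfg$consortia)
  # factor correlation: consortia sharing a feature get correlated factors
  fcor <- diag(nc)
  if (nc >= 2) {
    for (i in seq_len(nc - 1)) {
      for (j in (i + 1):nc) {
        if (length(intersect(consortium_feats[[i]],
                             consortium_feats[[j]])) > 0) {
          fcor[i, j] <- fcor[j, i] <- cfg$factor_cor
        }
      }
    }
  }

  rho <- cfg$rho_plant
  gam <- cfg$rho_bridge / ((1 + cfg$factor_cor) * sqrt(rho))
  delta2 <- 1 - gam^2 * 2 * (1 + cfg$factor_cor)
  if (length(bridge_ids) > 0 && delta2 < 0) {
    stop(sprintf(
      "rho_bridge = %.3g infeasible; must be <= sqrt(rho_plant * (1 + factor_cor) / 2) = %.3g",
      cfg$rho_bridge, sqrt(rho * (1 + cfg$factor_cor) / 2)), call. = FALSE)
  }

  draw_latents <- function(tp) {
    n <- n_subj
    f <- matrix(stats::rnorm(n * nc), n, nc)
    if (nc >= 1) f <- f %*% chol(fcor)
    z <- matrix(stats::rnorm(n * (cfg$n_taxa + cfg$n_vocs)), n,
                cfg$n_taxa + cfg$n_vocs,
                dimnames = list(NULL, c(taxa_ids, voc_ids)))
    # consortium loadings for taxa and vocs
    for (id in unique(unlist(consortium_feats))) {
      if (!(id %in% colnames(z))) next  # bucket members handled via blocks
      owners <- which(vapply(consortium_feats, function(f_) id %in% f_,
                             logical(1)))
      active <- vapply(owners, function(ci) {
        cs <- cfg$consortia[[ci]]
        is.null(cs$arm) && is.null(cs$timepoint)
      }, logical(1))
      owners_all <- owners
      eps <- stats::rnorm(n)
      if (length(owners_all) == 2 && all(active)) {
        z[, id] <- gam * (f[, owners_all[1]] + f[, owners_all[2]]) +
          sqrt(delta2) * eps
      } else {
        ci <- owners_all[1]
        cs <- cfg$consortia[[ci]]
        rows <- rep(TRUE, n)
        if (!is.null(cs$arm)) rows <- rows & subj$arm == cs$arm
        if (!is.null(cs$timepoint)) rows <- rows & (tp == cs$timepoint)
        z[, id] <- eps
        z[rows, id] <- sqrt(rho) * f[rows, ci] +
          sqrt(1 - rho) * eps[rows]
      }
    }
    # molecule-block latents (tied to a consortium factor when configured)
    zb <- matrix(stats::rnorm(n * cfg$n_buckets), n, cfg$n_buckets,
                 dimnames = list(NULL, bucket_ids))
    if (length(cfg$molecule_blocks) > 0) {
      for (b in seq_along(cfg$molecule_blocks)) {
        cols <- bucket_ids[cfg$molecule_blocks[[b]]]
        owner <- which(vapply(cfg$consortia,
                              function(cs) b %in% cs$blocks, logical(1)))
        m <- if (length(owner) >= 1) {
          sqrt(rho) * f[, owner[1]] + sqrt(1 - rho) * stats::rnorm(n)
        } else {
          stats::rnorm(n)
        }
        for (cl in cols) {
          zb[, cl] <- sqrt(cfg$block_cor) * m +
            sqrt(1 - cfg$block_cor) * stats::rnorm(n)
        }
      }
    }
    # arm effect: latent shift at Te in arm A on the configured blocks
    if (tp == "Te" && length(cfg$arm_effect_blocks) > 0) {
      aff <- bucket_ids[unlist(cfg$molecule_blocks[cfg$arm_effect_blocks])]
      rows <- subj$arm == "A"
      zb[rows, aff] <- zb[rows, aff] + cfg$arm_effect_size
    }
    list(z = z, zb = zb)
  }

  # log-scale locations: consortium features sit at comfortable abundance,
  # one dominant low-variance feature per compositional block stabilises the
  # renormalisation denominator, fillers spread over low abundances
  mu_taxa <- stats::setNames(seq(-1.5, 1.2, length.out = cfg$n_taxa),
                             taxa_ids)
  sd_taxa <- stats::setNames(rep(0.6, cfg$n_taxa), taxa_ids)
  cons_taxa <- intersect(unique(unlist(lapply(cfg$consortia, function(cs)
    taxa_ids[cs$taxa]))), taxa_ids)
  mu_taxa[cons_taxa] <- 1
  mu_taxa[taxa_ids[cfg$n_taxa]] <- 5.5
  sd_taxa[taxa_ids[cfg$n_taxa]] <- 0.05
  mu_voc <- stats::setNames(seq(-1, 0.8, length.out = cfg$n_vocs), voc_ids)
  sd_voc <- stats::setNames(rep(0.6, cfg$n_vocs), voc_ids)
  cons_voc <- intersect(unique(unlist(lapply(cfg$consortia, function(cs)
    voc_ids[cs$vocs]))), voc_ids)
  mu_voc[cons_voc] <- 1
  mu_voc[voc_ids[cfg$n_vocs]] <- 5
  sd_voc[voc_ids[cfg$n_vocs]] <- 0.05

  make_tables <- function(tp) {
    lat <- draw_latents(tp)
    n <- n_subj
    noise <- function(ncol_) matrix(stats::rnorm(n * ncol_, sd = cfg$noise_sd),
                                    n, ncol_)
    raw_taxa <- exp(sweep(sweep(lat$z[, taxa_ids, drop = FALSE] +
                                  noise(cfg$n_taxa), 2,
                                sd_taxa, "*"), 2, mu_taxa, "+"))
    raw_voc <- exp(sweep(sweep(lat$z[, voc_ids, drop = FALSE] +
                                 noise(cfg$n_vocs), 2,
                               sd_voc, "*"), 2, mu_voc, "+"))
    ra_taxa <- 100 * raw_taxa / rowSums(raw_taxa)
    ra_voc <- 100 * raw_voc / rowSums(raw_voc)
    buckets <- exp(4 + 0.5 * (lat$zb + noise(cfg$n_buckets)))
    sids <- paste0(subj$subject_id, "_", tp)
    rownames(ra_taxa) <- rownames(ra_voc) <- rownames(buckets) <- sids
    merge_tables(list(
      feature_table(ra_taxa, "microbiome", "percent_RA"),
      feature_table(ra_voc, "volatilome", "percent_RA"),
      feature_table(buckets, "metabolome_nmr", "intensity")))
  }

  t0 <- make_tables("T0")
  te <- make_tables("Te")
  design <- sample_design(
    sample_id = c(sample_ids(t0), sample_ids(te)),
    subject_id = rep(subj$subject_id, 2),
    sex = rep(subj$sex, 2),
    timepoint = rep(c("T0", "Te"), each = n_subj),
    arm = rep(subj$arm, 2))

  truth <- list(
    consortia = consortium_feats,
    bridge = bridge_ids,
    molecule_blocks = lapply(cfg$molecule_blocks, function(ix) bucket_ids[ix]),
    arm_affected = if (length(cfg$arm_effect_blocks) > 0) {
      bucket_ids[unlist(cfg$molecule_blocks[cfg$arm_effect_blocks])]
    } else {
      character(0)
    })
  list(t0 = t0, te = te, design = design, truth = truth, config = cfg)
}
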