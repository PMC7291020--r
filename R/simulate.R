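# Synthetic-batch generator with ground truth. Emulates a single-batch
# untargeted lipidomics study design: two biological groups, pooled-QC
# injections interleaved every few samples, solvent blanks, smooth
# injection-order drift, per-sample protein amounts, lognormal
# class-structured intensities and optional isomeric duplicates.

#' Simulation configuration
#'
#' Defaults describe the emulated study: n = 3 biological replicates per
#' group, one pooled QC every 4 samples (plus leading and trailing QCs),
#' 3 solvent blanks, ~16\% multiplicative QC noise, blanks at 1\% of
#' sample signal, 40-60 ug protein injected per sample.
#'
#' @param n_features_per_class named integer vector, features per lipid
#'   class.
#' @param n_per_group samples per group (default 3).
#' @param groups two group labels (case first).
#' @param n_blanks solvent blanks (default 3).
#' @param qc_interval one QC injected every this many samples (default 4).
#' @param drift \code{"none"}, \code{"linear"} or \code{"sinusoidal"}.
#' @param drift_magnitude peak-to-start fold change of the drift
#'   (default 2 when drift is on).
#' @param noise_cv multiplicative noise CV (default 0.16, matching
#'   typical intra-batch QC variability).
#' @param spikes data.frame with columns \code{selector} (a class code,
#'   a feature id, or \code{"random:k"} for k random features) and
#'   \code{fold_change}; NULL for a null batch.
#' @param blank_fraction blank signal as a fraction of mean sample
#'   signal (default 0.01).
#' @param protein_ug_range range protein per sample is drawn from
#'   (default 40-60 ug).
#' @param unannotated_fraction fraction of features given unparseable
#'   names (default 0.1).
#' @param isomer_dup_fraction fraction of annotated features emitted
#'   twice with the same annotation (default 0).
#' @param seed RNG seed.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_features_per_class = c(
  Cer = 30, HexCer = 20, Hex2Cer = 12, GM3 = 10, SM = 30,
  PC = 60, PE = 40, LPC = 16, PI = 16, PS = 12,
  CE = 20, TG = 40, DG = 16, FA = 16, CAR = 12),
  n_per_group = 3, groups = c("case", "control"),
  n_blanks = 3, qc_interval = 4,
  drift = c("none", "linear", "sinusoidal"), drift_magnitude = 2,
  noise_cv = 0.16, spikes = NULL, blank_fraction = 0.01,
  protein_ug_range = c(40, 60), unannotated_fraction = 0.1,
  isomer_dup_fraction = 0, seed = 1) {
  drift <- match.arg(drift)
  stopifnot(qc_interval >= 1, noise_cv > 0, n_per_group >= 1,
            length(groups) == 2, all(n_features_per_class >= 0))
  if (!is.null(spikes)) stopifnot(all(spikes$fold_change > 0))
  structure(list(n_features_per_class = n_features_per_class,
                 n_per_group = n_per_group, groups = groups,
                 n_blanks = n_blanks, qc_interval = qc_interval,
                 drift = drift, drift_magnitude = drift_magnitude,
                 noise_cv = noise_cv, spikes = spikes,
                 blank_fraction = blank_fraction,
                 protein_ug_range = protein_ug_range,
                 unannotated_fraction = unannotated_fraction,
                 isomer_dup_fraction = isomer_dup_fraction,
                 seed = seed),
            class = "sim_config")
}

# internal: drift multiplier as a function of injection order
drift_factor <- function(order, max_order, kind, magnitude) {
  switch(kind,
         none = rep(1, length(order)),
         linear = 1 + (magnitude - 1) * (order - 1) / (max_order - 1),
         sinusoidal = 1 + (magnitude - 1) / 2 *
           (1 + sin(2 * pi * order / max_order)))
}

# internal: lognormal multiplicative noise with a given CV
mult_noise <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Generate a synthetic batch with ground truth
#'
#' Feature base intensities are lognormal with class-specific location;
#' case-group means are the base times the true fold change; sample, QC
#' and blank intensities all carry multiplicative lognormal noise at
#' \code{noise_cv}; QCs follow the grand-mean (pooled) profile; the
#' drift factor multiplies every non-blank injection as a smooth
#' function of injection order; sample intensities scale with the drawn
#' protein amount. Deterministic given \code{cfg$seed}.
#'
#' @param cfg a [sim_config()].
#' @return list with \code{ft} (a [feature_table()], state raw) and
#'   \code{manifest} (list: per-feature truth data.frame, drift
#'   parameters, seed).
#' @export
generate_batch <- function(cfg) {
  set.seed(cfg$seed)
  classes <- rep(names(cfg$n_features_per_class), cfg$n_features_per_class)
  n_feat <- length(classes)

  # unique sum compositions per class (even carbons; odd/ether mixed in)
  name_of <- character(n_feat)
  truth_class <- classes
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    grid <- expand.grid(c = seq(28, 48, by = 2), d = 0:6)
    if (cl %in% c("LPC", "FA", "CAR"))
      grid <- expand.grid(c = seq(14, 26, by = 2), d = 0:4)
    if (cl == "TG") grid <- expand.grid(c = seq(44, 62, by = 2), d = 0:10)
    if (length(idx) > nrow(grid))
      grid <- expand.grid(c = seq(24, 60, by = 2), d = 0:12)
    pick <- grid[sample(nrow(grid), length(idx),
                        replace = length(idx) > nrow(grid)), ]
    ether <- if (cl %in% c("PC", "PE"))
      sample(c("", "O-", "P-"), length(idx), replace = TRUE,
             prob = c(0.7, 0.2, 0.1)) else rep("", length(idx))
    name_of[idx] <- sprintf("%s %s%d:%d", cl, ether, pick$c, pick$d)
  }
  unann <- stats::runif(n_feat) < cfg$unannotated_fraction
  name_of[unann] <- sprintf("w/o MS2:%04d", which(unann))
  truth_class[unann] <- NA_character_

  base <- stats::rlnorm(n_feat,
                        meanlog = 10 + as.numeric(factor(classes)) * 0.3,
                        sdlog = 1)
  true_fc <- rep(1, n_feat)
  feature_id <- sprintf("FT%05d", seq_len(n_feat))
  if (!is.null(cfg$spikes)) {
    for (i in seq_len(nrow(cfg$spikes))) {
      sel <- cfg$spikes$selector[i]
      idx <- if (grepl("^random:", sel)) {
        k <- as.integer(sub("^random:", "", sel))
        sample(n_feat, k)
      } else if (sel %in% classes) which(classes == sel)
      else which(feature_id == sel)
      if (!length(idx)) stop("spike selector matched nothing: ", sel)
      true_fc[idx] <- cfg$spikes$fold_change[i]
    }
  }

  # isomeric duplicates: re-emit a fraction of annotated rows
  if (cfg$isomer_dup_fraction > 0) {
    cand <- which(!unann)
    dup <- sample(cand, max(1L, round(cfg$isomer_dup_fraction * length(cand))))
    classes <- c(classes, classes[dup])
    truth_class <- c(truth_class, truth_class[dup])
    name_of <- c(name_of, name_of[dup])
    base <- c(base, base[dup] * stats::runif(length(dup), 0.2, 0.8))
    true_fc <- c(true_fc, true_fc[dup])
    n_feat <- length(base)
    feature_id <- sprintf("FT%05d", seq_len(n_feat))
  }

  # injection schedule: blanks, then QC | s s s s | QC | ... | QC
  n_samples <- 2L * cfg$n_per_group
  group_of <- sample(rep(cfg$groups, each = cfg$n_per_group))
  inj <- data.frame(injection_id = character(0), role = character(0),
                    group = character(0), stringsAsFactors = FALSE)
  add <- function(inj, id, role, group = "")
    rbind(inj, data.frame(injection_id = id, role = role, group = group,
                          stringsAsFactors = FALSE))
  for (b in seq_len(cfg$n_blanks))
    inj <- add(inj, sprintf("blank_%02d", b), "blank")
  qc_n <- 1L
  inj <- add(inj, sprintf("QC_%02d", qc_n), "qc"); qc_n <- qc_n + 1L
  for (s in seq_len(n_samples)) {
    inj <- add(inj, sprintf("s%02d_%s", s, group_of[s]), "sample", group_of[s])
    if (s %% cfg$qc_interval == 0L && s < n_samples) {
      inj <- add(inj, sprintf("QC_%02d", qc_n), "qc"); qc_n <- qc_n + 1L
    }
  }
  inj <- add(inj, sprintf("QC_%02d", qc_n), "qc")
  inj$order <- seq_len(nrow(inj))
  inj$protein_ug <- NA_real_
  is_s <- inj$role == "sample"
  inj$protein_ug[is_s] <- stats::runif(sum(is_s), cfg$protein_ug_range[1],
                                       cfg$protein_ug_range[2])

  max_order <- nrow(inj)
  dmul <- drift_factor(inj$order, max_order, cfg$drift, cfg$drift_magnitude)
  prot_ref <- mean(cfg$protein_ug_range)

  grand_mean <- base * (1 + true_fc) / 2     # pooled-QC expectation
  M <- matrix(0, n_feat, nrow(inj))
  for (j in seq_len(nrow(inj))) {
    mu <- switch(inj$role[j],
                 sample = base *
                   (if (inj$group[j] == cfg$groups[1]) true_fc else rep(1, n_feat)) *
                   (inj$protein_ug[j] / prot_ref),
                 qc = grand_mean,
                 blank = grand_mean * cfg$blank_fraction)
    d <- if (inj$role[j] == "blank") 1 else dmul[j]
    M[, j] <- mu * d * mult_noise(n_feat, cfg$noise_cv)
  }

  feats <- data.frame(feature_id = feature_id,
                      mz = round(stats::runif(n_feat, 400, 950), 4),
                      rt = round(stats::runif(n_feat, 0.8, 14.5), 3),
                      name = name_of,
                      id_score = round(stats::runif(n_feat, 71, 99), 1),
                      stringsAsFactors = FALSE)
  ft <- feature_table(feats, inj, M, state = "raw")
  manifest <- list(
    truth = data.frame(feature_id = feature_id, lipid_class = truth_class,
                       base_intensity = base, true_fold_change = true_fc,
                       stringsAsFactors = FALSE),
    drift = list(kind = cfg$drift, magnitude = cfg$drift_magnitude),
    noise_cv = cfg$noise_cv, seed = cfg$seed,
    groups = cfg$groups
  )
  list(ft = ft, manifest = manifest)
}

#' Evaluate recovery of spiked features
#'
#' Compares a result table against the simulator's ground truth:
#' precision at top-k of the impact-factor ranking (and any other
#' ranking column requested) and recall of true spikes at q < 0.05.
#'
#' @param stats per-feature results carrying \code{feature_id},
#'   \code{q_fdr} and \code{impact_factor}.
#' @param manifest the manifest from [generate_batch()].
#' @param k top-k for precision (default: number of true spikes).
#' @param rank_by column name to rank by, descending (default
#'   \code{"impact_factor"}).
#' @return list: \code{n_spiked}, \code{precision_at_k}, \code{recall_q05}.
#' @export
evaluate_recovery <- function(stats, manifest, k = NULL,
                              rank_by = "impact_factor") {
  truth <- manifest$truth
  spiked <- truth$feature_id[truth$true_fold_change != 1]
  if (!all(stats$feature_id %in% truth$feature_id))
    stop("results contain feature ids absent from the manifest")
  if (is.null(k)) k <- length(spiked)
  ord <- order(-stats[[rank_by]])
  topk <- stats$feature_id[ord][seq_len(min(k, nrow(stats)))]
  sig <- stats$feature_id[!is.na(stats$q_fdr) & stats$q_fdr < 0.05]
  list(n_spiked = length(spiked),
       precision_at_k = if (length(topk)) mean(topk %in% spiked) else NA_real_,
       recall_q05 = if (length(spiked)) mean(spiked %in% sig) else NA_real_)
}
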