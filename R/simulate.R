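#' Generate a synthetic community template
#'
#' Draws heavy-tailed taxon proportions from a log-normal distribution and
#' closes them to sum to one. The default spread (`lognormal_sigma = 4`)
#' produces the strong dominance structure typical of faecal communities:
#' the most abundant taxon holds a large share of the community and a
#' 2000-read sample observes on the order of a hundred taxa. Prevalence is
#' the probability of observing the taxon at least once in a multinomial
#' sample of `reference_depth` reads, used only for ranking taxa.
#'
#' @param n_taxa Number of template taxa (>= 10).
#' @param seed Integer seed; the template is deterministic given the seed.
#' @param lognormal_sigma Log-scale standard deviation (>= 0); 0 gives
#'   uniform proportions.
#' @param reference_depth Depth used to convert proportions to prevalence
#'   for ranking (default 2000 reads).
#' @return Object of class `sim_template`: `taxon_ids`, `proportions`
#'   (summing to 1), `prevalence`.
#' @export
synthetic_template <- function(n_taxa, seed, lognormal_sigma = 4,
                               reference_depth = 2000) {
  if (n_taxa < 10L) stop("n_taxa must be at least 10")
  if (lognormal_sigma < 0) stop("lognormal_sigma must be non-negative")
  p <- withr::with_seed(seed, exp(stats::rnorm(n_taxa, 0, lognormal_sigma)))
  p <- p / sum(p)
  structure(list(
    taxon_ids = sprintf("tax%04d", seq_len(n_taxa)),
    proportions = p,
    prevalence = 1 - (1 - p)^reference_depth
  ), class = "sim_template")
}

#' @export
print.sim_template <- function(x, ...) {
  cat(sprintf("<sim_template> %d taxa, top taxon %.1f%% of community\n",
              length(x$proportions), 100 * max(x$proportions)))
  invisible(x)
}

#' Define a case-control simulation scenario
#'
#' Bundles the parameters of one benchmark condition. The defaults other
#' than `n_per_group`, `effect_size` and `seed` are the benchmark protocol:
#' keep the 2000 most prevalent template taxa, spike 100 true-positive taxa,
#' sequence 2000 reads per sample, then remove taxa below 5% prevalence and
#' add a pseudocount of 1.
#'
#' @param n_per_group Samples per group (cases = controls).
#' @param effect_size Multiplicative spike (>= 1) applied to the
#'   true-positive taxa in the case group.
#' @param depth Reads per sample.
#' @param n_template_taxa Most prevalent template taxa retained.
#' @param n_true_positive Number of spiked taxa.
#' @param prevalence_filter Taxa nonzero in strictly fewer than this
#'   fraction of samples are removed in post-processing.
#' @param pseudocount Added to all counts in post-processing.
#' @param seed Integer seed for the draw.
#' @return Object of class `sim_scenario`.
#' @export
simulation_scenario <- function(n_per_group, effect_size, depth = 2000,
                                n_template_taxa = 2000,
                                n_true_positive = 100,
                                prevalence_filter = 0.05, pseudocount = 1,
                                seed) {
  stopifnot(n_per_group >= 1, effect_size >= 1, depth >= 1,
            n_true_positive <= n_template_taxa,
            prevalence_filter >= 0, prevalence_filter <= 1)
  structure(list(n_per_group = as.integer(n_per_group),
                 effect_size = effect_size, depth = as.integer(depth),
                 n_template_taxa = as.integer(n_template_taxa),
                 n_true_positive = as.integer(n_true_positive),
                 prevalence_filter = prevalence_filter,
                 pseudocount = pseudocount, seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Simulate a case-control metagenomic dataset from a template
#'
#' Template-based spike-in generation: the scenario's most prevalent
#' template taxa are kept (ties broken by abundance, then id); a random set
#' of true-positive taxa is drawn uniformly among them; control samples are
#' multinomial draws at the scenario depth from the (re-closed) template
#' proportions; case samples draw from the template with the true-positive
#' proportions multiplied by the effect size and re-closed. Raw counts per
#' sample always total the depth exactly. Post-processing (prevalence
#' filter + pseudocount) is a separate, composable step,
#' [benchmark_postprocess()].
#'
#' @param template A `sim_template` (or any list with `taxon_ids`,
#'   `proportions`, `prevalence`).
#' @param scenario A `sim_scenario`.
#' @return Object of class `sim_dataset`: `table` (a `composition_table` of
#'   raw counts, controls first then cases), `labels` (factor
#'   control/case), `true_positive_taxa`, `scenario`, and `postprocessed =
#'   FALSE`.
#' @export
simulate_case_control <- function(template, scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  Tn <- length(template$proportions)
  if (scenario$n_template_taxa > Tn)
    stop("scenario keeps ", scenario$n_template_taxa,
         " taxa but the template only has ", Tn)
  ord <- order(-template$prevalence, -template$proportions,
               template$taxon_ids)
  keep <- sort(ord[seq_len(scenario$n_template_taxa)])
  ids <- template$taxon_ids[keep]
  p0 <- template$proportions[keep]
  p0 <- p0 / sum(p0)

  withr::with_seed(scenario$seed, {
    tp <- sort(sample(seq_along(ids), scenario$n_true_positive))
    p1 <- p0
    p1[tp] <- p1[tp] * scenario$effect_size
    p1 <- p1 / sum(p1)
    n <- scenario$n_per_group
    counts <- cbind(stats::rmultinom(n, scenario$depth, p0),
                    stats::rmultinom(n, scenario$depth, p1))
  })
  counts <- t(counts)
  labels <- factor(rep(c("control", "case"), each = scenario$n_per_group),
                   levels = c("control", "case"))
  tab <- composition_table(counts,
                           sample_ids = sprintf("s%04d", seq_len(nrow(counts))),
                           taxon_ids = ids)
  structure(list(table = tab, labels = labels,
                 true_positive_taxa = ids[tp], scenario = scenario,
                 postprocessed = FALSE),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d samples x %d taxa, effect %g, %d true positives%s\n",
              nrow(x$table$values), ncol(x$table$values),
              x$scenario$effect_size, length(x$true_positive_taxa),
              if (x$postprocessed) " (post-processed)" else " (raw counts)"))
  invisible(x)
}

#' Benchmark post-processing: prevalence filter + pseudocount
#'
#' Removes taxa nonzero in strictly fewer than `prevalence_filter` of the
#' samples (a taxon present in exactly that fraction is kept), then adds
#' the pseudocount to every entry. Thresholds default to the ones recorded
#' in the dataset's scenario.
#'
#' @param dataset A `sim_dataset` with raw counts.
#' @param prevalence_filter,pseudocount Override the scenario values.
#' @return The dataset with `table` replaced by the processed table and
#'   `postprocessed = TRUE`.
#' @export
benchmark_postprocess <- function(dataset,
                                  prevalence_filter = dataset$scenario$prevalence_filter,
                                  pseudocount = dataset$scenario$pseudocount) {
  stopifnot(inherits(dataset, "sim_dataset"))
  prev <- colMeans(dataset$table$values > 0)
  keep <- which(prev >= prevalence_filter)
  if (length(keep) < 2L)
    stop("fewer than 2 taxa pass the prevalence filter")
  dataset$table <- impute_zeros(subset_taxa(dataset$table, keep), pseudocount)
  dataset$postprocessed <- TRUE
  dataset
}

#' Synthetic cross-sectional data with a planted two-taxon signal
#'
#' Generates log-abundances as independent standard normals and an outcome
#' driven by the single log-ratio of taxa 1 and 2:
#' linear predictor `effect * (log X_1 - log X_2)`, with Bernoulli
#' (binomial family) or additive-noise (gaussian family) response. Used to
#' validate parameter recovery: a correct fit selects taxa 1 and 2 with
#' opposite signs.
#'
#' @param n Samples.
#' @param n_taxa Taxa (>= 3).
#' @param effect Strength of the planted log-contrast.
#' @param family `"binomial"` or `"gaussian"`.
#' @param noise_sd Residual sd for the gaussian family.
#' @param seed Integer seed.
#' @return List with `table` (a `composition_table`), `y`, and
#'   `true_taxa` (ids of taxa 1 and 2).
#' @export
simulate_logcontrast_data <- function(n = 100, n_taxa = 10, effect = 3,
                                      family = c("binomial", "gaussian"),
                                      noise_sd = 0.5, seed) {
  family <- match.arg(family)
  stopifnot(n_taxa >= 3)
  withr::with_seed(seed, {
    logx <- matrix(stats::rnorm(n * n_taxa), n, n_taxa)
    lp <- effect * (logx[, 1L] - logx[, 2L])
    y <- if (family == "binomial") {
      factor(ifelse(stats::rbinom(n, 1, stats::plogis(lp)) == 1,
                    "case", "control"), levels = c("control", "case"))
    } else {
      lp + stats::rnorm(n, 0, noise_sd)
    }
  })
  ids <- sprintf("tax%02d", seq_len(n_taxa))
  tab <- composition_table(exp(logx), taxon_ids = ids)
  list(table = tab, y = y, true_taxa = ids[1:2])
}

#' Synthetic longitudinal data with divergent trajectories
#'
#' Generates per-subject log-abundance trajectories: every taxon follows a
#' flat subject-specific level with observation noise; in the case group
#' taxon 1's level is elevated by `effect`. Taxon 2 is a low-noise stable
#' reference, the remaining taxa are noisy, so the cleanest discriminating
#' log-ratio trajectory is taxon 1 over taxon 2. Observation times are
#' subject-specific (uniform over the window, plus both endpoints).
#'
#' @param n_per_group Subjects per group.
#' @param n_taxa Taxa (>= 3).
#' @param n_times Observations per subject (>= 2).
#' @param window Time window `c(l1, l2)`.
#' @param effect Case-group elevation of taxon 1 (log scale).
#' @param seed Integer seed.
#' @return List with `table` (a `longitudinal_table` of positive
#'   abundances), per-subject outcome `y` (named factor), and `true_taxa`.
#' @export
simulate_trajectory_data <- function(n_per_group = 15, n_taxa = 8,
                                     n_times = 6, window = c(0, 90),
                                     effect = 2, seed) {
  stopifnot(n_taxa >= 3, n_times >= 2)
  window <- check_window(window)
  m <- 2L * n_per_group
  subjects <- sprintf("subj%03d", seq_len(m))
  group <- rep(c("control", "case"), each = n_per_group)
  obs_sd <- c(0.4, 0.15, rep(1.2, n_taxa - 2L))
  subj_sd <- c(0.4, 0.15, rep(0.8, n_taxa - 2L))
  withr::with_seed(seed, {
    rows <- lapply(seq_len(m), function(s) {
      tt <- sort(c(window, stats::runif(max(0L, n_times - 2L),
                                        window[1L], window[2L])))
      base <- stats::rnorm(n_taxa, 0, subj_sd)
      if (group[s] == "case") base[1L] <- base[1L] + effect
      logx <- t(vapply(tt, function(t.)
        base + stats::rnorm(n_taxa, 0, obs_sd), numeric(n_taxa)))
      list(times = tt, logx = logx)
    })
  })
  values <- exp(do.call(rbind, lapply(rows, `[[`, "logx")))
  times <- unlist(lapply(rows, `[[`, "times"))
  subj <- rep(subjects, each = n_times)
  ids <- sprintf("tax%02d", seq_len(n_taxa))
  lt <- longitudinal_table(values,
                           sample_ids = paste0(subj, "_t", stats::ave(times, subj, FUN = seq_along)),
                           taxon_ids = ids, subject_ids = subj, times = times)
  y <- factor(group, levels = c("control", "case"))
  names(y) <- subjects
  list(table = lt, y = y, true_taxa = ids[1:2])
}
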