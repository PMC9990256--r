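save_if_requested <- function(p, file, width = 7, height = 5) {
  if (!is.null(file)) ggplot2::ggsave(file, p, width = width, height = height)
  p
}

#' Plot the cross-validation accuracy curve
#'
#' Cross-validated metric (AUC or MSE) with one-standard-error bars against
#' the log penalization parameter, annotated with the number of selected
#' log-ratio pairs at each lambda, and vertical lines at `lambda_min` and
#' `lambda_1se`.
#'
#' @param fit A `penalized_fit`.
#' @param file Optional path; written by extension (png/pdf/svg).
#' @return A ggplot object.
#' @export
plot_cv_curve <- function(fit, file = NULL) {
  stopifnot(inherits(fit, "penalized_fit"))
  df <- data.frame(log_lambda = log(fit$lambda), cv_mean = fit$cv_mean,
                   cv_se = fit$cv_se, nzero = fit$nzero)
  ylab <- if (fit$metric == "auc") "cross-validation AUC" else "cross-validation MSE"
  ytop <- max(df$cv_mean + df$cv_se)
  yrange <- diff(range(df$cv_mean - df$cv_se, ytop))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = log_lambda, y = cv_mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = cv_mean - cv_se,
                                        ymax = cv_mean + cv_se),
                           colour = "grey60", width = 0) +
    ggplot2::geom_point(colour = "firebrick", size = 1) +
    ggplot2::geom_vline(xintercept = log(c(fit$lambda_min, fit$lambda_1se)),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = nzero), y = ytop + 0.08 * yrange,
                       size = 2.2, colour = "grey30") +
    ggplot2::labs(x = expression(log(lambda)), y = ylab,
                  title = sprintf("%d-fold cross-validation (alpha = %g)",
                                  fit$nfolds, fit$alpha)) +
    ggplot2::theme_bw()
  save_if_requested(p, file)
}

#' Plot the taxa of a signature
#'
#' Horizontal bar chart of the zero-sum coefficients of the selected taxa,
#' sorted by coefficient; positive (G1) bars green, negative (G2) red.
#'
#' @param sig A `coda_signature`.
#' @param file Optional output path.
#' @return A ggplot object (an informative empty plot when no taxon is
#'   selected).
#' @export
plot_signature <- function(sig, file = NULL) {
  stopifnot(inherits(sig, "coda_signature"))
  sel <- sig$theta[sig$theta != 0]
  if (length(sel) == 0L) {
    p <- ggplot2::ggplot() +
      ggplot2::annotate("text", x = 0, y = 0,
                        label = "empty signature: no taxa selected") +
      ggplot2::theme_void()
    return(save_if_requested(p, file))
  }
  df <- data.frame(taxon = names(sel), theta = unname(sel),
                   group = ifelse(sel > 0, "G1", "G2"))
  df$taxon <- factor(df$taxon, levels = df$taxon[order(df$theta)])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = theta, y = taxon, fill = group)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(G1 = "forestgreen", G2 = "firebrick"),
                               name = "balance group") +
    ggplot2::labs(x = "coefficient (theta)", y = NULL,
                  title = "Microbial signature") +
    ggplot2::theme_bw()
  save_if_requested(p, file)
}

#' Plot predictions against the outcome
#'
#' For a binary outcome, a box plot and a density plot of the signature
#' scores by group (stacked with patchwork); for a continuous outcome, a
#' scatter plot of scores against the outcome. The apparent accuracy is
#' shown in the title.
#'
#' @param sig A `coda_signature` carrying `scores` and `y`.
#' @param file Optional output path.
#' @return A ggplot / patchwork object.
#' @export
plot_prediction <- function(sig, file = NULL) {
  stopifnot(inherits(sig, "coda_signature"))
  if (is.null(sig$scores) || is.null(sig$y))
    stop("signature carries no scores/outcome; fit it with coda_signature()")
  if (sig$family == "binomial") {
    df <- data.frame(score = unname(sig$scores),
                     group = factor(as.character(sig$y)))
    ttl <- sprintf("apparent AUC = %.3f, cv AUC = %.3f (se %.4f)",
                   sig$apparent_metric, sig$cv_metric_mean, sig$cv_metric_se)
    pal <- c("darkorange", "steelblue")[seq_len(nlevels(df$group))]
    box <- ggplot2::ggplot(df, ggplot2::aes(x = group, y = score, fill = group)) +
      ggplot2::geom_boxplot(alpha = 0.7) +
      ggplot2::scale_fill_manual(values = pal, guide = "none") +
      ggplot2::labs(title = ttl, x = NULL, y = "signature score") +
      ggplot2::theme_bw()
    dens <- ggplot2::ggplot(df, ggplot2::aes(x = score, fill = group)) +
      ggplot2::geom_density(alpha = 0.5) +
      ggplot2::scale_fill_manual(values = pal) +
      ggplot2::labs(x = "signature score", y = "density") +
      ggplot2::theme_bw()
    p <- patchwork::wrap_plots(box, dens, ncol = 1)
  } else {
    df <- data.frame(score = unname(sig$scores), y = as.numeric(sig$y))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = score, y = y)) +
      ggplot2::geom_point(colour = "steelblue") +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           colour = "grey40") +
      ggplot2::labs(title = sprintf("apparent R^2 = %.3f", sig$apparent_metric),
                    x = "signature score", y = "outcome") +
      ggplot2::theme_bw()
  }
  save_if_requested(p, file)
}

#' Plot per-subject signature trajectories
#'
#' One thin curve per subject, coloured by outcome group, with thick
#' per-group pointwise mean curves and a horizontal reference line at zero
#' (scores above zero mean the positive-group taxa dominate the balance).
#'
#' @param traj A `signature_trajectories` object from
#'   [signature_trajectory()].
#' @param file Optional output path.
#' @return A ggplot object.
#' @export
plot_signature_curves <- function(traj, file = NULL) {
  stopifnot(inherits(traj, "signature_trajectories"))
  long <- data.frame(
    subject = rep(traj$subject_ids, each = length(traj$grid)),
    time = rep(traj$grid, times = length(traj$subject_ids)),
    value = as.vector(t(traj$curves)),
    group = rep(as.character(traj$y), each = length(traj$grid)))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = time, y = value, group = subject,
                                          colour = group)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_line(alpha = 0.35, linewidth = 0.3, na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c("darkorange", "steelblue"),
                                 name = NULL) +
    ggplot2::labs(x = "time", y = "signature (log-contrast) value",
                  title = "Signature trajectories") +
    ggplot2::theme_bw()
  if (!is.null(traj$group_means)) {
    means <- data.frame(
      group = rep(rownames(traj$group_means), each = length(traj$grid)),
      time = rep(traj$grid, times = nrow(traj$group_means)),
      value = as.vector(t(traj$group_means)))
    p <- p + ggplot2::geom_line(
      data = means,
      ggplot2::aes(x = time, y = value, group = group, colour = group),
      linewidth = 1.4, na.rm = TRUE)
  }
  save_if_requested(p, file)
}
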