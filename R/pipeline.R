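# End-to-end orchestration: load or simulate a cohort, fit the harmonic
# models (standard and robust, unaligned and best-phase aligned), run the
# circular analysis of best phases, compare amplitudes between sources and
# best conditions against sham, and write a machine-readable report.

#' Read a comprehension-score CSV
#'
#' Expects columns `subject`, `source` (`target`/`distractor`/`sham`),
#' `phase_deg`, `n_keywords`, `n_correct`; the comprehension score `cs` is
#' derived as `100 * n_correct / n_keywords` (an explicit `cs` column is
#' accepted too). Schema violations are reported with row numbers.
#'
#' @param path CSV path.
#' @return A `cohort_scores` data frame.
#' @export
read_scores <- function(path) {
  if (!file.exists(path))
    stop(sprintf("scores file '%s' does not exist", path), call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0)
    stop(sprintf("scores file '%s' is empty; expected columns subject, source, phase_deg, n_keywords, n_correct",
                 path), call. = FALSE)
  need <- c("subject", "source", "phase_deg")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(sprintf("scores file '%s' is missing columns: %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!"cs" %in% names(d)) {
    if (!all(c("n_keywords", "n_correct") %in% names(d)))
      stop("need either a `cs` column or both `n_keywords` and `n_correct`",
           call. = FALSE)
    d$cs <- 100 * d$n_correct / d$n_keywords
  }
  bad_src <- which(!d$source %in% c("target", "distractor", "sham"))
  if (length(bad_src))
    stop(sprintf("invalid source at row(s) %s",
                 paste(utils::head(bad_src, 5), collapse = ", ")),
         call. = FALSE)
  bad_cs <- which(!is.finite(d$cs) | d$cs < 0 | d$cs > 100)
  if (length(bad_cs))
    stop(sprintf("comprehension score outside [0, 100] at row(s) %s",
                 paste(utils::head(bad_cs, 5), collapse = ", ")),
         call. = FALSE)
  bad_ph <- which(d$source != "sham" & !d$phase_deg %in% c(0, 90, 180, 270))
  if (length(bad_ph))
    stop(sprintf("phase_deg must be 0/90/180/270 at row(s) %s",
                 paste(utils::head(bad_ph, 5), collapse = ", ")),
         call. = FALSE)
  for (src in intersect(c("target", "distractor"), unique(d$source))) {
    ds <- d[d$source == src, ]
    cnt <- table(ds$subject)
    if (any(cnt != 4))
      stop(sprintf("incomplete design for source '%s': subject(s) %s lack the four phases",
                   src, paste(names(cnt)[cnt != 4], collapse = ", ")),
           call. = FALSE)
  }
  structure(d, class = c("cohort_scores", "data.frame"))
}

#' Write a cohort scores CSV
#'
#' @param scores a `cohort_scores` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(as.data.frame(scores)[, c("subject", "source",
                                             "phase_deg", "n_keywords",
                                             "n_correct", "cs")],
                   path, row.names = FALSE)
  invisible(path)
}

default_config <- function() {
  list(
    simulate = list(preset = "study", seed = 1),
    scores_csv = NULL,
    sources = c("target", "distractor"),
    methods = c("ols", "robust"),
    n_boot_r2 = 2000,
    n_boot_amplitude = 2000,
    watson_n_sim = 499,
    concentration_n_perm = 1999,
    seed = 1,
    figures = FALSE
  )
}

#' Run the full phase-modulation analysis pipeline
#'
#' Executes, in order: score loading (or cohort simulation), per-source
#' mean-centering, harmonic fits by standard and robust regression with
#' FDR-corrected coefficient tables, amplitude/phase extraction, bootstrap
#' r2 comparison of the two regression methods, best-phase alignment and
#' aligned refits, circular analysis of best phases (summary, Rayleigh
#' test, von Mises fit with Watson goodness of fit), between-source
#' amplitude comparison and concentration homogeneity, and the sham ANOVA.
#'
#' @param config either a configuration list (see Details), a path to a
#'   YAML/JSON configuration file, or `NULL` for defaults. Recognised
#'   fields: `scores_csv` (path; otherwise a cohort is simulated with
#'   `simulate$seed`), `sources`, `methods`, `n_boot_r2`,
#'   `n_boot_amplitude`, `watson_n_sim`, `concentration_n_perm`, `seed`,
#'   `figures`.
#' @param out_dir optional directory to write the report to (see
#'   [write_report()]).
#' @return A list of class `study_report`.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL) {
  cfg <- default_config()
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  if (is.list(config)) cfg[names(config)] <- config

  scores <- if (!is.null(cfg$scores_csv)) read_scores(cfg$scores_csv)
            else generate_cohort(seed = cfg$simulate$seed %||% cfg$seed)

  per_source <- list()
  for (src in cfg$sources) {
    centered <- center_scores(scores, src)
    fits <- list()
    for (m in cfg$methods) fits[[m]] <- fit_harmonic(centered, method = m)
    boot <- bootstrap_r2_compare(centered, n_boot = cfg$n_boot_r2,
                                 seed = cfg$seed)
    aligned <- align_to_best_phase(scores, src)
    aligned_fits <- list()
    for (m in cfg$methods)
      aligned_fits[[m]] <- fit_harmonic(aligned, method = m)
    best <- best_phase_per_subject(scores, src)
    circ <- list(
      summary = circular_summary(best),
      rayleigh = rayleigh_test(best),
      von_mises = fit_von_mises(best, n_sim = cfg$watson_n_sim,
                                seed = cfg$seed))
    per_source[[src]] <- list(fits = fits, bootstrap_r2 = boot,
                              aligned_fits = aligned_fits,
                              best_phases = best, circular = circ)
  }

  amp_cmp <- if (all(c("target", "distractor") %in% cfg$sources))
    compare_amplitudes(scores, n_boot = cfg$n_boot_amplitude,
                       seed = cfg$seed) else NULL
  conc <- if (all(c("target", "distractor") %in% cfg$sources))
    concentration_homogeneity(per_source$target$best_phases,
                              per_source$distractor$best_phases,
                              n_perm = cfg$concentration_n_perm,
                              seed = cfg$seed) else NULL
  sham <- if ("sham" %in% scores$source) compare_to_sham(scores) else NULL

  report <- structure(list(
    config = cfg, scores = scores, per_source = per_source,
    amplitude_comparison = amp_cmp, concentration = conc,
    sham_anova = sham,
    provenance = list(package_version =
                        as.character(utils::packageVersion("tacsphase")),
                      seed = cfg$seed)),
    class = "study_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

fit_table <- function(fits) {
  do.call(rbind, lapply(names(fits), function(m) {
    tb <- fits[[m]]$coefficients
    tb$method <- m
    tb
  }))
}

#' Write a study report to disk
#'
#' Writes `report.json` (the full structured report), one TSV coefficient
#' table per source and model family under `tables/` (rows A0/B1/B2/A2
#' with estimate, CI and FDR-corrected p, plus an F/p/r2 footer mirrored
#' in the JSON), the scores CSV, and, if `ggplot2` is available and
#' figures were requested, score-versus-phase and best-phase-histogram
#' figures under `figures/`.
#'
#' @param report a `study_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tables"), showWarnings = FALSE)
  json <- list(config = report$config[setdiff(names(report$config),
                                              "figures")],
               provenance = report$provenance)
  for (src in names(report$per_source)) {
    ps <- report$per_source[[src]]
    json[[src]] <- list(
      fits = lapply(ps$fits, function(f)
        list(coefficients = f$coefficients, a1 = f$a1,
             phi1_deg = f$phi1_deg, a1_ci = f$a1_ci, r2 = f$r2, f = f$f,
             p_model = f$p_model)),
      aligned_fits = lapply(ps$aligned_fits, function(f)
        list(coefficients = f$coefficients, r2 = f$r2, f = f$f,
             p_model = f$p_model)),
      bootstrap_r2_p = ps$bootstrap_r2$p,
      best_phases_deg = as.numeric(ps$best_phases),
      circular = list(mean_deg = ps$circular$summary$mean_deg,
                      R = ps$circular$summary$R,
                      ang_dev_rad = ps$circular$summary$ang_dev_rad,
                      rayleigh_p = ps$circular$rayleigh$p,
                      mu_deg = ps$circular$von_mises$mu_deg,
                      kappa = ps$circular$von_mises$kappa,
                      watson_p = ps$circular$von_mises$watson_p))
    utils::write.table(fit_table(ps$fits),
                       file.path(dir, "tables",
                                 sprintf("fit_%s.tsv", src)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(fit_table(ps$aligned_fits),
                       file.path(dir, "tables",
                                 sprintf("fit_%s_aligned.tsv", src)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$amplitude_comparison))
    json$amplitude_comparison <- report$amplitude_comparison[
      c("a1_a", "a1_b", "diff", "se_boot", "p")]
  if (!is.null(report$concentration))
    json$concentration <- report$concentration[c("ratio", "R_a", "R_b", "p")]
  if (!is.null(report$sham_anova))
    json$sham_anova <- report$sham_anova[c("f", "df", "df_resid", "p")]
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")
  write_scores(report$scores, file.path(dir, "scores.csv"))
  if (isTRUE(report$config$figures) &&
      requireNamespace("ggplot2", quietly = TRUE)) {
    dir.create(file.path(dir, "figures"), showWarnings = FALSE)
    for (src in names(report$per_source)) {
      centered <- center_scores(report$scores, src)
      fit <- report$per_source[[src]]$fits[[
        if ("robust" %in% names(report$per_source[[src]]$fits)) "robust"
        else 1]]
      ggplot2::ggsave(
        file.path(dir, "figures", sprintf("phase_fit_%s.png", src)),
        plot_phase_fit(centered, fit), width = 5, height = 4, dpi = 150)
      ggplot2::ggsave(
        file.path(dir, "figures", sprintf("best_phase_%s.png", src)),
        plot_best_phase_hist(report$per_source[[src]]$best_phases,
                             report$per_source[[src]]$circular$von_mises),
        width = 5, height = 4, dpi = 150)
    }
  }
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report\n============\n")
  for (src in names(x$per_source)) {
    cat(sprintf("\n-- source: %s --\n", src))
    for (m in names(x$per_source[[src]]$fits))
      print(x$per_source[[src]]$fits[[m]])
    print(x$per_source[[src]]$circular$summary)
    print(x$per_source[[src]]$circular$rayleigh)
    print(x$per_source[[src]]$circular$von_mises)
  }
  if (!is.null(x$amplitude_comparison)) print(x$amplitude_comparison)
  if (!is.null(x$concentration)) print(x$concentration)
  if (!is.null(x$sham_anova)) print(x$sham_anova)
  invisible(x)
}

#' Score-versus-phase figure with the fitted cosine
#'
#' @param centered a `centered_scores` data frame.
#' @param fit a `harmonic_fit`.
#' @return A ggplot object.
#' @export
plot_phase_fit <- function(centered, fit) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  grid <- data.frame(phase_deg = seq(0, 360, by = 2))
  grid$dcs <- fit$a1 * cos(deg2rad(grid$phase_deg - fit$phi1_deg))
  ggplot2::ggplot(centered,
                  ggplot2::aes(x = .data$phase_deg, y = .data$dcs)) +
    ggplot2::geom_jitter(width = 6, alpha = 0.5, colour = "grey40") +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 3) +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::scale_x_continuous(breaks = c(0, 90, 180, 270, 360)) +
    ggplot2::labs(x = "stimulation phase (deg)",
                  y = expression(Delta * "CS (percentage points)"))
}

#' Best-phase histogram with the fitted von Mises density
#'
#' @param best_phases a `phase_sample`.
#' @param vm a `von_mises_fit`.
#' @return A ggplot object.
#' @export
plot_best_phase_hist <- function(best_phases, vm) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- data.frame(phase = as.numeric(best_phases))
  dens <- data.frame(phase = seq(0, 360, by = 2))
  dens$y <- dvonmises(deg2rad(dens$phase), deg2rad(vm$mu_deg), vm$kappa) *
    pi / 2 * length(best_phases)  # scale to counts per 90-deg bin
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase)) +
    ggplot2::geom_histogram(breaks = seq(-45, 360, by = 90),
                            fill = "grey70", colour = "grey30") +
    ggplot2::geom_line(data = dens, ggplot2::aes(y = .data$y),
                       colour = "red") +
    ggplot2::scale_x_continuous(breaks = c(0, 90, 180, 270, 360)) +
    ggplot2::labs(x = "best phase (deg)", y = "subjects")
}
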