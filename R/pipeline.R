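# End-to-end analysis: efflux cohort -> slopes -> per-channel normalization
# -> group statistics; transfer pairs -> rates -> per-channel normalization.
# run_pipeline() wraps the same steps around delimited-text inputs driven by
# a YAML configuration.

#' Analyze an efflux cohort end to end
#'
#' For every efflux trace: fit the slope `k` over the analysis window and
#' divide by the genotype-group-mean open-channel count `g/gamma` from the
#' electrophysiology table (efflux cells are not patched, so per-cell counts
#' are unavailable by design). Group statistics are then computed on the
#' normalized values and, separately, on the `n_po` estimates.
#'
#' The default is one common early window (the first 300 s) for all cells:
#' it keeps the linearized efflux model uniformly valid across genotypes, so
#' that slow exponential curvature — which accumulates faster in
#' high-permeability cells — does not shrink their slopes differentially.
#' Pass `window = NULL` for per-trace adaptive selection via
#' [select_linear_window()].
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()], or a list
#'   with elements `efflux` (list of [fluorescence_trace()]s carrying
#'   `genotype` labels) and `ephys` (data.frame with `genotype`, `g_ns`,
#'   `gamma_ps`).
#' @param alpha Significance level for the statistics (default 0.05).
#' @param window Common fit window `c(t_start, t_end)` (s), default
#'   `c(0, 300)`; `NULL` selects a window per trace.
#' @param ... Passed to [select_linear_window()] (e.g. `min_points`,
#'   `exclude`).
#' @return An object of class `efflux_analysis`: `estimates` (per-cell
#'   data.frame), `group_summary` (mean +/- SE per genotype),
#'   `stats_permeability` and `stats_n_po` ([compare_groups()] reports), and
#'   `n_po_group` (group-mean counts used).
#' @export
analyze_efflux_cohort <- function(cohort, alpha = 0.05, window = c(0, 300),
                                  ...) {
  traces <- cohort$efflux
  ephys <- cohort$ephys
  stopifnot(length(traces) >= 1, is.data.frame(ephys),
            all(c("genotype", "g_ns", "gamma_ps") %in% names(ephys)))
  if (!"n_po" %in% names(ephys)) {
    ephys$n_po <- estimate_channel_count(ephys$g_ns, ephys$gamma_ps)
  }
  n_po_group <- tapply(ephys$n_po, ephys$genotype, mean)
  rows <- lapply(traces, function(tr) {
    fit <- tryCatch(fit_efflux_slope(tr, window = window, ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      return(data.frame(genotype = tr$genotype, cell = tr$label,
                        slope_k_au_s = NA_real_, r_squared = NA_real_,
                        window_start_s = NA_real_, window_end_s = NA_real_,
                        n_po_group = NA_real_, value_per_channel = NA_real_,
                        note = conditionMessage(fit)))
    }
    npo <- n_po_group[[tr$genotype]]
    if (is.null(npo)) stop("no electrophysiology for genotype ", tr$genotype,
                           call. = FALSE)
    norm <- normalize_hemichannel(fit, npo)
    data.frame(genotype = tr$genotype, cell = tr$label,
               slope_k_au_s = fit$slope_k, r_squared = fit$r_squared,
               window_start_s = fit$window[1], window_end_s = fit$window[2],
               n_po_group = npo, value_per_channel = norm$value, note = "")
  })
  est <- do.call(rbind, rows)
  ok <- !is.na(est$value_per_channel)
  grp <- factor(est$genotype[ok])
  summ <- do.call(rbind, lapply(levels(grp), function(lv) {
    v <- est$value_per_channel[ok][grp == lv]
    data.frame(genotype = lv, n = length(v), mean = mean(v),
               se = stats::sd(v) / sqrt(length(v)))
  }))
  structure(list(
    estimates = est,
    group_summary = summ,
    n_po_group = n_po_group,
    stats_permeability = compare_groups(est$value_per_channel[ok],
                                        est$genotype[ok], alpha = alpha),
    stats_n_po = compare_groups(ephys$n_po, ephys$genotype, alpha = alpha),
    alpha = alpha), class = "efflux_analysis")
}

#' @export
print.efflux_analysis <- function(x, ...) {
  cat("<efflux_analysis>\n")
  cat("Per-channel normalized slope (a.u./s per open hemichannel):\n")
  print(x$group_summary, digits = 4)
  cat(sprintf("\nPermeability comparison: %s branch, omnibus p = %.3g\n",
              x$stats_permeability$branch, x$stats_permeability$omnibus_p))
  cat(sprintf("n*Po comparison:         %s branch, omnibus p = %.3g\n",
              x$stats_n_po$branch, x$stats_n_po$omnibus_p))
  invisible(x)
}

#' Analyze a set of donor/recipient transfer pairs
#'
#' Fits `P_j/Vol_2` for each pair — with the recipient exponential when the
#' donor reaches steady state, falling back to the ODE-discretization
#' estimator otherwise — and normalizes per GJ channel by `g_j/gamma_j`.
#'
#' @param pairs List of pair descriptors: each a list with `donor` and
#'   `recipient` ([fluorescence_trace()]s), `gj_ns`, `gamma_j_ps`, optional
#'   `genotype`, optional `exclude` blocker intervals.
#' @param alpha Significance level for group statistics (default 0.05);
#'   statistics are only computed when >= 2 genotypes have >= 3 pairs.
#' @return List with `estimates` (per-pair data.frame) and `stats`
#'   ([compare_groups()] report or `NULL`).
#' @export
analyze_transfer_pairs <- function(pairs, alpha = 0.05) {
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    exclude <- p$exclude %||% list()
    t_ss <- detect_donor_steady_state(p$donor)
    est <- if (!is.na(t_ss)) {
      fit_recipient_exponential(p$donor, p$recipient, t_ss = t_ss,
                                exclude = exclude)
    } else {
      estimate_rate_discretized(p$donor, p$recipient, exclude = exclude)
    }
    norm <- normalize_gj(est, p$gj_ns, p$gamma_j_ps)
    data.frame(pair = p$label %||% sprintf("pair%02d", i),
               genotype = p$genotype %||% NA_character_,
               method = est$method, rate_per_s = est$rate,
               gj_ns = p$gj_ns, gamma_j_ps = p$gamma_j_ps,
               n_channels = norm$n_po_used,
               value_per_channel = norm$value)
  })
  est <- do.call(rbind, rows)
  stats_report <- NULL
  tab <- table(est$genotype[!is.na(est$genotype)])
  if (length(tab) >= 2 && all(tab >= 3)) {
    keep <- !is.na(est$genotype)
    stats_report <- compare_groups(est$value_per_channel[keep],
                                   est$genotype[keep], alpha = alpha)
  }
  list(estimates = est, stats = stats_report)
}

#' Run the full pipeline from a configuration
#'
#' Drives efflux and/or transfer analysis from delimited-text inputs. The
#' configuration (YAML file or equivalent list) has sections:
#' \describe{
#'   \item{efflux}{`traces`: trace-table paths (long format with `roi` and
#'     optionally `genotype` columns); `background`: scalar f0 per file
#'     (recycled); `ephys`: path to a table with `genotype`, `g_ns`,
#'     `gamma_ps` columns, or `n_po`: named group-mean counts.}
#'   \item{transfer}{`pairs`: list of entries with `donor`, `recipient`
#'     (paths), `gj_ns`, `gamma_j_ps`, optional `genotype`, `background`,
#'     `blockers` (list of `[start, end]` s).}
#'   \item{alpha}{significance level, default 0.05.}
#' }
#' Per-cell estimates, group summaries (mean +/- SE), and the statistics
#' report are written as delimited text when `out_dir` is given.
#'
#' @param config Path to a YAML file or a list with the structure above.
#' @param out_dir Optional output directory (created if needed).
#' @return List with elements `efflux` ([analyze_efflux_cohort()] result)
#'   and/or `transfer` ([analyze_transfer_pairs()] result).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  alpha <- config$alpha %||% 0.05
  out <- list()
  if (!is.null(config$efflux)) {
    ef <- config$efflux
    if (is.null(ef$traces) || !length(ef$traces)) {
      stop("efflux section lists no trace tables", call. = FALSE)
    }
    bg <- rep(ef$background %||% 0, length.out = length(ef$traces))
    traces <- unlist(lapply(seq_along(ef$traces), function(i) {
      read_trace_table(ef$traces[[i]], background = bg[i])
    }), recursive = FALSE)
    if (any(is.na(vapply(traces, function(tr) tr$genotype, character(1))))) {
      stop("every efflux trace needs a genotype label", call. = FALSE)
    }
    ephys <- if (!is.null(ef$ephys)) {
      read_delim_checked(ef$ephys, c("g_ns", "gamma_ps"))
    } else if (!is.null(ef$n_po)) {
      data.frame(genotype = rep(names(ef$n_po), each = 3),
                 g_ns = NA_real_, gamma_ps = NA_real_,
                 n_po = rep(unlist(ef$n_po), each = 3))
    } else {
      stop("efflux section needs 'ephys' table or 'n_po' group means",
           call. = FALSE)
    }
    out$efflux <- analyze_efflux_cohort(list(efflux = traces, ephys = ephys),
                                        alpha = alpha)
  }
  if (!is.null(config$transfer)) {
    pairs <- lapply(config$transfer$pairs, function(p) {
      bg <- p$background %||% 0
      list(donor = read_trace_table(p$donor, background = bg)[[1]],
           recipient = read_trace_table(p$recipient, background = bg)[[1]],
           gj_ns = p$gj_ns, gamma_j_ps = p$gamma_j_ps,
           genotype = p$genotype,
           exclude = lapply(p$blockers %||% list(), as.numeric),
           label = p$label)
    })
    out$transfer <- analyze_transfer_pairs(pairs, alpha = alpha)
  }
  if (!length(out)) stop("config has neither efflux nor transfer section",
                         call. = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(out$efflux)) {
      utils::write.csv(out$efflux$estimates,
                       file.path(out_dir, "efflux_estimates.csv"),
                       row.names = FALSE)
      utils::write.csv(out$efflux$group_summary,
                       file.path(out_dir, "efflux_group_summary.csv"),
                       row.names = FALSE)
      write_stats_report(out$efflux$stats_permeability,
                         file.path(out_dir, "efflux_stats.csv"))
    }
    if (!is.null(out$transfer)) {
      utils::write.csv(out$transfer$estimates,
                       file.path(out_dir, "transfer_estimates.csv"),
                       row.names = FALSE)
      if (!is.null(out$transfer$stats)) {
        write_stats_report(out$transfer$stats,
                           file.path(out_dir, "transfer_stats.csv"))
      }
    }
  }
  out
}

# statistics report as delimited text: one omnibus line then pairwise rows
write_stats_report <- function(report, path) {
  pw <- report$pairwise
  pw$test <- report$branch
  pw$omnibus_p <- report$omnibus_p
  utils::write.csv(pw, path, row.names = FALSE)
  invisible(path)
}
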