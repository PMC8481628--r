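#' Summarise an ensemble into figure-level tables
#'
#' Aggregates a [run_ensemble()] result into across-run summaries: mean and
#' standard deviation (sample SD, `n - 1` denominator) of STAY counts and of
#' the first-entry GO-minus-STAY value gaps per episode and state, mean
#' weight trajectories, STAY-count histograms, and truncation counts. Gaps
#' at states a run never reached within an episode are missing and excluded
#' from the corresponding mean/SD.
#'
#' @param ensemble A `procrasim_ensemble`.
#' @return An object of class `procrasim_summary`: a list of tibbles
#'   `stays`, `gaps`, `w`, `stay_hist`, plus `n_runs`, `n_truncated` and the
#'   originating `config`.
#' @examples
#' s <- summarize_ensemble(run_ensemble(sim_config(n_runs = 20)))
#' subset(s$stays, episode == 1)
#' @export
summarize_ensemble <- function(ensemble) {
  stopifnot(inherits(ensemble, "procrasim_ensemble"))
  cfg <- ensemble$config
  if (cfg$n_runs < 1 || cfg$vacation_episodes < 1) {
    stop("cannot summarise an empty ensemble")
  }
  n <- cfg$chain$n
  E <- cfg$vacation_episodes
  grid <- expand.grid(episode = seq_len(E), state = seq_len(n - 1),
                      KEEP.OUT.ATTRS = FALSE)

  cell_stats <- function(arr, ep, st) {
    v <- arr[, ep, st]
    c(mean(v, na.rm = TRUE),
      if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) else 0)
  }

  stay_stats <- mapply(function(ep, st) cell_stats(ensemble$stay_counts, ep, st),
                       grid$episode, grid$state)
  stays <- tibble::tibble(episode = grid$episode, state = grid$state,
                          mean = stay_stats[1, ], sd = stay_stats[2, ])

  gaps <- do.call(rbind, lapply(
    c(approximated = "gap_approx", estimated_true = "gap_true"),
    function(field) {
      st <- mapply(function(ep, s) cell_stats(ensemble[[field]], ep, s),
                   grid$episode, grid$state)
      tibble::tibble(episode = grid$episode, state = grid$state,
                     mean = st[1, ], sd = st[2, ])
    }))
  gaps <- tibble::tibble(
    system = rep(c("approximated", "estimated_true"), each = nrow(grid)),
    gaps)

  w_school <- tibble::tibble(
    phase = "school",
    episode = rep(seq_len(nrow(ensemble$w_school)), n),
    state = rep(seq_len(n), each = nrow(ensemble$w_school)),
    mean_w = as.vector(ensemble$w_school))
  w_vac <- tibble::tibble(
    phase = "vacation",
    episode = rep(seq_len(E), n),
    state = rep(seq_len(n), each = E),
    mean_w = as.vector(apply(ensemble$w_vacation, c(2, 3),
                             mean, na.rm = TRUE)))
  w <- rbind(w_school, w_vac)

  hist_rows <- lapply(seq_len(nrow(grid)), function(i) {
    tab <- table(ensemble$stay_counts[, grid$episode[i], grid$state[i]])
    tibble::tibble(episode = grid$episode[i], state = grid$state[i],
                   n_stay = as.integer(names(tab)),
                   count = as.integer(tab))
  })
  stay_hist <- do.call(rbind, hist_rows)

  structure(list(stays = stays, gaps = gaps, w = w, stay_hist = stay_hist,
                 n_runs = cfg$n_runs,
                 n_truncated = sum(ensemble$truncated),
                 config = cfg),
            class = "procrasim_summary")
}

#' @export
print.procrasim_summary <- function(x, ...) {
  cat(sprintf("<procrasim_summary> %d runs, %d vacation episodes (%d truncated)\n",
              x$n_runs, max(x$stays$episode), x$n_truncated))
  ep1 <- subset(x$stays, x$stays$episode == 1)
  cat("episode-1 mean STAY per state:",
      paste(sprintf("S%d=%.2f", ep1$state, ep1$mean), collapse = ", "), "\n")
  invisible(x)
}

#' Analytic vacation-start baselines
#'
#' The "episode-0" reference points of the gap trajectories: the
#' GO-minus-STAY action-value differences under the non-procrastinating
#' policy, computed in closed form. The true gap uses the closed-form state
#' values; the approximated gap is evaluated at the TD fixed-point weight
#' `w* = R - cost * sum(gamma^j, j = 1..n-1)`.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `state`, `system`, `gap`, plus the
#'   fixed-point weight as attribute `w_star`.
#' @examples
#' baseline_gaps(sim_config())
#' @export
baseline_gaps <- function(config) {
  n <- config$chain$n
  gamma <- config$gamma
  cost <- config$chain$cost
  v <- closed_form_values(n, gamma, config$chain$reward, cost)$value
  x <- goal_based_features(n, gamma)
  w_star <- config$chain$reward - cost * sum(gamma^seq_len(n - 1))
  k <- seq_len(n - 1)
  out <- tibble::tibble(
    state = rep(k, 2),
    system = rep(c("approximated", "estimated_true"), each = n - 1),
    gap = c(gamma * w_star * x[k + 1] - cost - gamma * w_star * x[k],
            gamma * v[k + 1] - cost - gamma * v[k]))
  attr(out, "w_star") <- w_star
  out
}

#' Export an ensemble summary to disk
#'
#' Writes tidy CSV tables (`stays.csv`, `gaps.csv`, `w.csv`,
#' `stay_hist.csv`), a JSON run manifest holding the fully resolved
#' configuration, seed and summary conventions, and (optionally) PDF figures
#' of the STAY-count and value-gap trajectories. Re-running the simulation
#' from the manifest reproduces the summary exactly.
#'
#' @param summary A `procrasim_summary`.
#' @param dir Destination directory (created if needed).
#' @param plots Also write figures (requires ggplot2)?
#' @return Invisibly, the paths written.
#' @export
export_summary <- function(summary, dir, plots = FALSE) {
  stopifnot(inherits(summary, "procrasim_summary"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (tab in c("stays", "gaps", "w", "stay_hist")) {
    p <- file.path(dir, paste0(tab, ".csv"))
    write.csv(summary[[tab]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(config_manifest(summary$config,
                                       n_truncated = summary$n_truncated),
                       manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, manifest_path)
  if (plots) {
    if (!requireNamespace("ggplot2", quietly = TRUE)) {
      warning("ggplot2 not available; skipping plots")
    } else {
      p1 <- file.path(dir, "stay_counts.pdf")
      ggplot2::ggsave(p1, plot_stay_counts(summary), width = 6, height = 4)
      p2 <- file.path(dir, "value_gaps.pdf")
      ggplot2::ggsave(p2, plot_value_gaps(summary), width = 6, height = 4)
      paths <- c(paths, p1, p2)
    }
  }
  invisible(paths)
}

#' Serialise a configuration as a manifest list
#'
#' @param config A [sim_config()].
#' @param ... Extra fields appended to the manifest.
#' @return A named list suitable for JSON/YAML serialisation.
#' @export
config_manifest <- function(config, ...) {
  list(package = "procrasim",
       version = as.character(packageVersion("procrasim")),
       n_states = config$chain$n,
       reward = config$chain$reward,
       cost = config$chain$cost,
       gamma = config$gamma,
       beta = config$beta,
       lr_mode = config$lr_mode,
       lr_constant = config$lr_constant,
       school_episodes = config$school_episodes,
       vacation_episodes = config$vacation_episodes,
       n_runs = config$n_runs,
       seed = config$seed,
       max_steps_per_episode = config$max_steps_per_episode,
       variant = unclass(config$variant),
       sd_convention = "sample (n - 1 denominator)",
       ...)
}

#' Rebuild a configuration from a manifest file
#'
#' @param path Path to a `manifest.json` written by [export_summary()] (a
#'   YAML config file with the same keys also works).
#' @return A [sim_config()].
#' @export
config_from_manifest <- function(path) {
  m <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  sim_config(
    chain = task_chain(m$n_states %||% 5, m$reward %||% 1, m$cost %||% 0.1),
    gamma = m$gamma %||% 0.85,
    beta = m$beta %||% 20,
    lr_mode = m$lr_mode %||% "scheduled",
    lr_constant = m$lr_constant %||% 0.2,
    school_episodes = m$school_episodes %||% 20,
    vacation_episodes = m$vacation_episodes %||% 20,
    n_runs = m$n_runs %||% 10000,
    seed = m$seed %||% 1,
    variant = if (is.null(m$variant)) variant_config("none") else
      do.call(variant_config, m$variant),
    max_steps_per_episode = m$max_steps_per_episode %||% 10000)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot mean STAY counts over vacation episodes
#'
#' @param summary A `procrasim_summary`.
#' @return A ggplot object.
#' @export
plot_stay_counts <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  d <- summary$stays
  d$state <- factor(paste0("S", d$state))
  ggplot2::ggplot(d, ggplot2::aes(episode, mean, colour = state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "vacation episode", y = "mean STAY count",
                  colour = "state") +
    ggplot2::theme_minimal()
}

#' Plot first-entry value gaps over vacation episodes
#'
#' @param summary A `procrasim_summary`.
#' @return A ggplot object.
#' @export
plot_value_gaps <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  d <- summary$gaps
  d$state <- factor(paste0("S", d$state))
  ggplot2::ggplot(d, ggplot2::aes(episode, mean, colour = state, linetype = system)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "vacation episode", y = "GO - STAY value gap",
                  colour = "state", linetype = "value system") +
    ggplot2::theme_minimal()
}
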