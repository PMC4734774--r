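#' Simulation configuration
#'
#' @param stop_size Target total cell count at which a run stops (>= 2).
#' @param max_events Safety cap on the number of birth/death events; a run
#'   hitting it is reported with outcome `"truncated"`, never silently.
#' @param condition_on_survival If `TRUE`, ensemble collection discards
#'   extinct runs.
#' @param required_successful Minimum number of successful mutations for a
#'   run to qualify in an ensemble (3 for tree studies, 0 otherwise).
#' @param track_time If `TRUE` (default) exponential waiting times are
#'   drawn and clone origin times recorded; all summary statistics are
#'   size-indexed, so `FALSE` skips the time draws (flagged in the output).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(stop_size = 5e4, max_events = 2e8,
                       condition_on_survival = TRUE,
                       required_successful = 0L, track_time = TRUE) {
  stopifnot(stop_size >= 2, max_events > 0, required_successful >= 0)
  structure(list(stop_size = as.integer(stop_size),
                 max_events = as.numeric(max_events),
                 condition_on_survival = isTRUE(condition_on_survival),
                 required_successful = as.integer(required_successful),
                 track_time = isTRUE(track_time)),
            class = "sim_config")
}

#' Simulate one clonal expansion with passenger mutation
#'
#' Exact Gillespie simulation of the multi-type birth-death branching
#' process: starting from a single founder (type 0) cell, each event is a
#' division with probability b/(b+d) or a death otherwise, hitting a cell
#' drawn uniformly (clone chosen proportional to its size); at a division,
#' with probability `u` one daughter acquires a new passenger mutation and
#' founds a new clone, recorded with the total population size z present
#' just before it appeared. The run ends at extinction, at `stop_size`
#' cells, or at the `max_events` safety cap.
#'
#' Randomness comes from R's RNG stream: call [set.seed()] (or pass `seed`)
#' for a bit-reproducible trajectory.
#'
#' @inheritParams fixation_probability
#' @param config A [sim_config()] object.
#' @param seed Optional integer seed applied via [set.seed()] before the run.
#' @return An object of class `clone_genealogy`: a list with
#'   `clones` (data.frame: `id`, `parent`, `origin_z`, `origin_time`,
#'   `count`, `subtree_count`), `n_cells`, `n_events`, `outcome`
#'   (`"complete"`, `"extinct"` or `"truncated"`), `params`, `config`.
#' @examples
#' p <- branching_params(b = 0.25, d = 0.18)
#' g <- simulate_clone_genealogy(p, sim_config(stop_size = 500), seed = 1)
#' g$outcome
#' @export
simulate_clone_genealogy <- function(params, config = sim_config(),
                                     seed = NULL) {
  params <- as_branching_params(params)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  raw <- .gillespie_run(params$b, params$d, params$u, config$stop_size,
                        config$max_events, config$track_time)
  clones <- data.frame(id = seq_along(raw$parent) - 1L,
                       parent = raw$parent,
                       origin_z = raw$origin_z,
                       origin_time = if (config$track_time) raw$origin_time
                                     else rep(NA_real_, length(raw$parent)),
                       count = raw$count,
                       subtree_count = raw$subtree_count)
  structure(list(clones = clones,
                 n_cells = raw$n_cells,
                 n_events = raw$n_events,
                 outcome = raw$outcome,
                 time_tracked = config$track_time,
                 params = params, config = config),
            class = "clone_genealogy")
}

#' @export
print.clone_genealogy <- function(x, ...) {
  cat(sprintf("Clone genealogy: %d clones, %g cells, %g events, outcome %s\n",
              nrow(x$clones), x$n_cells, x$n_events, x$outcome))
  invisible(x)
}

#' Classify successful and fixed mutations in a finished run
#'
#' A mutation is "successful" if its lineage never goes extinct. At a finite
#' stop size this is resolved by the exact limit law of the linear
#' birth-death process: each of the m cells carrying the mutation (and each
#' of the m_nc = M - m non-carriers) independently leaves a surviving
#' lineage with probability 1 - delta, and a surviving lineage's long-run
#' size weight is Exp(1) on a common scale. One draw
#' `S_m ~ Binomial(m, 1 - delta)`, `S_nc ~ Binomial(m_nc, 1 - delta)` per
#' mutation therefore yields, coherently:
#' * successful: `S_m >= 1` (probability 1 - delta^m);
#' * fixed: successful and `S_nc == 0` (probability delta^m_nc);
#' * eventual frequency: 1 if fixed, else `Beta(S_m, S_nc)`.
#'
#' Successful mutations are labeled 1, 2, ... by origin time, and each is
#' assigned its nearest successful ancestor (0 = founder lineage) as parent
#' label.
#'
#' @param genealogy A `clone_genealogy` from [simulate_clone_genealogy()]
#'   with outcome `"complete"`.
#' @inheritParams fixation_probability
#' @param seed Optional integer seed for the classification draws.
#' @return A data.frame (mutation report), one row per successful mutation:
#'   `k`, `clone_id`, `parent_label`, `origin_z`, `origin_time`,
#'   `frequency` (carrier cells / total at stop), `eventual_frequency`,
#'   `fixed`.
#' @export
classify_successful <- function(genealogy, params = genealogy$params,
                                seed = NULL) {
  stopifnot(inherits(genealogy, "clone_genealogy"))
  if (genealogy$outcome == "extinct")
    stop("cannot classify an extinct run; condition on survival first",
         call. = FALSE)
  if (genealogy$outcome == "truncated")
    stop("run was truncated at max_events; increase the cap", call. = FALSE)
  params <- as_branching_params(params)
  if (!is.null(seed)) set.seed(seed)
  cl <- genealogy$clones
  M <- genealogy$n_cells
  mut <- cl[cl$id != 0L, , drop = FALSE] # clone 0 is the founder type, not a mutation
  n <- nrow(mut)
  empty <- data.frame(k = integer(), clone_id = integer(),
                      parent_label = integer(), origin_z = integer(),
                      origin_time = numeric(), frequency = numeric(),
                      eventual_frequency = numeric(), fixed = logical())
  if (n == 0L) return(empty)
  m <- mut$subtree_count
  s_m <- stats::rbinom(n, m, 1 - params$delta)
  s_nc <- stats::rbinom(n, as.integer(M) - m, 1 - params$delta)
  successful <- s_m >= 1L
  if (!any(successful)) return(empty)
  ok <- which(successful)
  fixed <- s_nc[ok] == 0L
  ev <- ifelse(fixed, 1,
               stats::rbeta(length(ok), s_m[ok], pmax(s_nc[ok], 1L)))

  # labels by origin time (ids are already in origin order)
  labels <- integer(nrow(cl)); labels[mut$id[ok] + 1L] <- seq_along(ok)
  succ_flag <- logical(nrow(cl)); succ_flag[mut$id[ok] + 1L] <- TRUE
  parent_label <- vapply(mut$id[ok], function(id) {
    a <- cl$parent[id + 1L]
    while (a > 0L && !succ_flag[a + 1L]) a <- cl$parent[a + 1L]
    if (a <= 0L) 0L else labels[a + 1L]
  }, integer(1L))

  data.frame(k = seq_along(ok),
             clone_id = mut$id[ok],
             parent_label = parent_label,
             origin_z = mut$origin_z[ok],
             origin_time = mut$origin_time[ok],
             frequency = m[ok] / M,
             eventual_frequency = ev,
             fixed = fixed)
}

#' Ensemble of surviving simulated expansions
#'
#' Repeats [simulate_clone_genealogy()] + [classify_successful()] until
#' `n_surviving` qualifying runs are collected (non-extinct; at least
#' `config$required_successful` successful mutations), discarding the rest.
#' The expected number of attempts is about `n / (1 - delta)`; collection
#' aborts if attempts exceed ten times that.
#'
#' @inheritParams fixation_probability
#' @param config A [sim_config()].
#' @param n_surviving Number of qualifying runs to collect (>= 1).
#' @param seed Optional integer seed set once before collection (runs then
#'   consume one common RNG stream, so the ensemble is reproducible).
#' @param max_k Track the first `max_k` successful mutations' frequencies.
#' @return A list of class `sim_ensemble`:
#'   `frequencies` (list over k of per-run eventual frequencies),
#'   `stop_frequencies` (same, frequencies at stop size),
#'   `fixation_fraction` (per k), `fixation_se`,
#'   `tree_index` (per-run topology index of the first three successful
#'   mutations, `NA` when fewer than 3), `tree_freq`, `tree_se`,
#'   `mean_successful`, `attempts`, `n_extinct`, `n_unqualified`.
#' @export
simulate_ensemble <- function(params, config = sim_config(),
                              n_surviving = 1000L, seed = NULL,
                              max_k = 3L) {
  params <- as_branching_params(params)
  stopifnot(inherits(config, "sim_config"), n_surviving >= 1)
  if (!is.null(seed)) set.seed(seed)
  max_attempts <- ceiling(10 * n_surviving / (1 - params$delta))

  freqs <- lapply(seq_len(max_k), function(i) numeric(0))
  stop_freqs <- freqs
  fixed <- lapply(seq_len(max_k), function(i) logical(0))
  tree_index <- integer(0)
  n_successful <- integer(0)
  attempts <- 0L; n_extinct <- 0L; n_unqualified <- 0L; collected <- 0L

  while (collected < n_surviving) {
    if (attempts >= max_attempts)
      stop("exceeded ", max_attempts, " attempts while collecting ",
           n_surviving, " surviving runs (survival prob ~ ",
           format(1 - params$delta), ")", call. = FALSE)
    attempts <- attempts + 1L
    g <- simulate_clone_genealogy(params, config)
    if (g$outcome == "extinct") { n_extinct <- n_extinct + 1L; next }
    if (g$outcome == "truncated")
      stop("simulation truncated at max_events = ", config$max_events,
           call. = FALSE)
    rep <- classify_successful(g, params)
    if (nrow(rep) < config$required_successful) {
      n_unqualified <- n_unqualified + 1L; next
    }
    collected <- collected + 1L
    for (k in seq_len(min(max_k, nrow(rep)))) {
      freqs[[k]] <- c(freqs[[k]], rep$eventual_frequency[k])
      stop_freqs[[k]] <- c(stop_freqs[[k]], rep$frequency[k])
      fixed[[k]] <- c(fixed[[k]], rep$fixed[k])
    }
    tree_index <- c(tree_index,
                    if (nrow(rep) >= 3L)
                      classify_tree(rep$parent_label[2L],
                                    min(rep$parent_label[3L], 2L))
                    else NA_integer_)
    n_successful <- c(n_successful, nrow(rep))
  }

  fix_frac <- vapply(fixed, function(f) if (length(f)) mean(f) else NA_real_,
                     numeric(1L))
  fix_se <- vapply(fixed, function(f)
    if (length(f)) sqrt(stats::var(f) / length(f)) else NA_real_, numeric(1L))
  ti <- tree_index[!is.na(tree_index)]
  tree_freq <- if (length(ti)) tabulate(ti, 6L) / length(ti) else rep(NA_real_, 6L)
  tree_se <- sqrt(tree_freq * (1 - tree_freq) / max(length(ti), 1L))
  structure(list(frequencies = freqs, stop_frequencies = stop_freqs,
                 fixation_fraction = fix_frac, fixation_se = fix_se,
                 tree_index = tree_index,
                 tree_freq = stats::setNames(tree_freq, paste0("p", 1:6)),
                 tree_se = tree_se, n_trees = length(ti),
                 mean_successful = mean(n_successful),
                 attempts = attempts, n_extinct = n_extinct,
                 n_unqualified = n_unqualified,
                 n_surviving = collected,
                 params = params, config = config),
            class = "sim_ensemble")
}

#' @export
print.sim_ensemble <- function(x, ...) {
  cat(sprintf(
    "Ensemble: %d surviving runs (%d attempts, %d extinct, %d unqualified)\n",
    x$n_surviving, x$attempts, x$n_extinct, x$n_unqualified))
  cat(sprintf("mean successful mutations per run: %.2f\n", x$mean_successful))
  if (!all(is.na(x$tree_freq)))
    cat("tree frequencies (%):",
        paste(sprintf("%.1f", 100 * x$tree_freq), collapse = " "), "\n")
  invisible(x)
}

#' Export a clone genealogy as a Newick string
#'
#' Clone ids label the tips/internal nodes and live cell counts are attached
#' as branch annotations (`id_count` labels), so the string round-trips the
#' clone table's tree structure.
#'
#' @param genealogy A `clone_genealogy`.
#' @return A single Newick string.
#' @export
genealogy_to_newick <- function(genealogy) {
  stopifnot(inherits(genealogy, "clone_genealogy"))
  cl <- genealogy$clones
  kids <- split(cl$id[cl$id != 0L], cl$parent[cl$id != 0L])
  build <- function(id) {
    lab <- paste0(id, "_", cl$count[id + 1L])
    ch <- kids[[as.character(id)]]
    if (is.null(ch) || !length(ch)) return(lab)
    paste0("(", paste(vapply(ch, build, character(1L)), collapse = ","),
           ")", lab)
  }
  paste0(build(0L), ";")
}
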