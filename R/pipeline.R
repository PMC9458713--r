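#' Per-subject state detection
#'
#' Runs the windowing, per-window cartographic profiling and the k = 2
#' state clustering for one subject.
#'
#' @param bold a `bold_ts` or T x N matrix.
#' @param window_len,step window geometry (TRs).
#' @param gamma modularity resolution.
#' @param louvain_iter Louvain restarts per window.
#' @param pc_bins,z_bins,z_range histogram geometry.
#' @param kmeans_restarts k-means restarts.
#' @param seed integer seed (windows get derived sub-seeds).
#' @return list: `dfc`, `profiles`, `assignment`, `metrics` (one-row data
#'   frame from [temporal_metrics()]).
#' @export
subject_states <- function(bold, window_len = 63L, step = 1L, gamma = 1,
                           louvain_iter = 100L, pc_bins = 10L, z_bins = 10L,
                           z_range = c(-5, 5), kmeans_restarts = 50L,
                           seed = 1L) {
  dfc <- dynamic_fc(bold, window_len, step)
  profiles <- lapply(seq_along(dfc$windows), function(w)
    cartographic_profile(dfc$windows[[w]], gamma = gamma,
                         n_iter = louvain_iter, seed = derive_seed(seed, w),
                         pc_bins = pc_bins, z_bins = z_bins, z_range = z_range))
  assignment <- cluster_states(profiles, seed = derive_seed(seed, 0L),
                               n_restarts = kmeans_restarts)
  list(dfc = dfc, profiles = profiles, assignment = assignment,
       metrics = temporal_metrics(assignment$labels))
}

#' Per-subject control energies from detected states
#'
#' State-mean FC, sum-connectivity state vectors and the four-transition
#' energy suite on the subject's structural connectome. Returns `NULL` with
#' a warning if either state is absent.
#'
#' @param sc structural connectome.
#' @param dfc the subject's `dynamic_fc`.
#' @param assignment the subject's `state_assignment` (or label vector).
#' @param rho,T_horizon,n_steps control parameters.
#' @param normalize unit-normalize state vectors (see [transition_suite()]).
#' @export
subject_energies <- function(sc, dfc, assignment, rho = 1, T_horizon = 1,
                             n_steps = 1001L, normalize = FALSE) {
  smf <- state_mean_fc(dfc, assignment)
  if (any(smf$absent)) {
    warning("state absent (", paste(names(which(smf$absent)), collapse = ", "),
            "); subject skipped for control analysis", call. = FALSE)
    return(NULL)
  }
  xi <- state_vector(smf$Integrated)
  xs <- state_vector(smf$Segregated)
  suite <- transition_suite(sc, xi, xs, rho = rho, T_horizon = T_horizon,
                            n_steps = n_steps, normalize = normalize)
  list(state_mean = smf, x_integrated = xi, x_segregated = xs, suite = suite)
}

#' Hedges' g standardized mean difference
#'
#' Pooled-SD standardized difference with the small-sample correction
#' J = 1 - 3 / (4 df - 1), df = n1 + n2 - 2.
#'
#' @param x,y numeric samples.
#' @return g (positive when mean(x) > mean(y)).
#' @export
hedges_g <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop_invalid("need >= 2 observations per group")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df)
  J <- 1 - 3 / (4 * df - 1)
  J * (mean(x) - mean(y)) / sp
}

# Route a two-or-more-group comparison: Shapiro-Wilk in every group at
# alpha = 0.05 decides parametric vs rank-based, overridable.
route_test <- function(values, group, force = c("auto", "parametric", "rank")) {
  force <- match.arg(force)
  group <- factor(group)
  normal <- if (force == "auto") {
    all(vapply(split(values, group), function(v) {
      if (length(unique(v)) < 3 || length(v) < 3) return(FALSE)
      shapiro.test(v)$p.value >= 0.05
    }, logical(1)))
  } else force == "parametric"
  if (nlevels(group) == 2L) {
    if (normal) {
      tt <- t.test(values ~ group)
      list(test = "t", statistic = unname(tt$statistic), p = tt$p.value)
    } else {
      wt <- suppressWarnings(wilcox.test(values ~ group))
      list(test = "mann-whitney", statistic = unname(wt$statistic), p = wt$p.value)
    }
  } else {
    if (normal) {
      a <- anova(aov(values ~ group))
      list(test = "anova", statistic = a$`F value`[1], p = a$`Pr(>F)`[1])
    } else {
      kw <- kruskal.test(values, group)
      list(test = "kruskal-wallis", statistic = unname(kw$statistic), p = kw$p.value)
    }
  }
}

#' Group-level statistics for temporal metrics and energies
#'
#' Routes each temporal metric to a parametric or rank-based group test
#' (Shapiro-Wilk at alpha = 0.05 decides; override with `force`), compares
#' each of the four log energies between the two contrast groups with
#' Hedges' g for the Integrated-to-Segregated transition, and summarises the
#' within-subject persistence contrast (II vs SS, paired).
#'
#' @param metrics data frame with `group` and metric columns
#'   (`fraction_integrated`, `dwell_integrated`, `dwell_segregated`,
#'   `n_transitions`).
#' @param energies data frame with `subject_id`, `group` and `log_IS`,
#'   `log_SI`, `log_II`, `log_SS`, or `NULL` to skip.
#' @param contrast the two group labels compared for effect sizes.
#' @param force test routing override.
#' @return a `group_stats_report` list: `temporal` (data frame),
#'   `energy` (data frame with Hedges' g), `persistence` (paired II vs SS
#'   F and p).
#' @export
group_stats <- function(metrics, energies = NULL,
                        contrast = c("VH", "nonVH"),
                        force = c("auto", "parametric", "rank")) {
  force <- match.arg(force)
  grp <- factor(metrics$group)
  keep_groups <- names(which(table(grp) >= 2))
  if (length(keep_groups) < 2) stop_invalid("need >= 2 groups with >= 2 subjects")
  if (length(keep_groups) < nlevels(grp))
    warning("groups with < 2 subjects excluded: ",
            paste(setdiff(levels(grp), keep_groups), collapse = ", "),
            call. = FALSE)
  metrics <- metrics[metrics$group %in% keep_groups, , drop = FALSE]

  metric_cols <- intersect(c("fraction_integrated", "dwell_integrated",
                             "dwell_segregated", "n_transitions"),
                           names(metrics))
  temporal <- do.call(rbind, lapply(metric_cols, function(mc) {
    r <- route_test(metrics[[mc]], metrics$group, force)
    data.frame(metric = mc, test = r$test, statistic = r$statistic, p = r$p)
  }))

  energy <- NULL; persistence <- NULL
  if (!is.null(energies) && nrow(energies)) {
    e1 <- energies[energies$group == contrast[1], , drop = FALSE]
    e2 <- energies[energies$group == contrast[2], , drop = FALSE]
    energy <- do.call(rbind, lapply(c("log_IS", "log_SI", "log_II", "log_SS"),
      function(col) {
        r <- route_test(c(e1[[col]], e2[[col]]),
                        rep(contrast, c(nrow(e1), nrow(e2))), force)
        data.frame(energy = col, test = r$test, statistic = r$statistic,
                   p = r$p,
                   hedges_g = if (col == "log_IS") hedges_g(e1[[col]], e2[[col]])
                              else NA_real_)
      }))
    # within-subject persistence contrast: repeated-measures F on II vs SS
    d <- energies$log_II - energies$log_SS
    tt <- t.test(d)
    persistence <- list(F = unname(tt$statistic)^2,
                        df = c(1, length(d) - 1),
                        p = tt$p.value,
                        mean_diff = mean(d))
  }
  structure(list(temporal = temporal, energy = energy,
                 persistence = persistence, contrast = contrast),
            class = "group_stats_report")
}

#' @export
print.group_stats_report <- function(x, ...) {
  cat("group_stats_report\n temporal metrics:\n")
  print(x$temporal, row.names = FALSE)
  if (!is.null(x$energy)) {
    cat(sprintf(" energies (%s vs %s):\n", x$contrast[1], x$contrast[2]))
    print(x$energy, row.names = FALSE)
    cat(sprintf(" persistence II vs SS: F(1,%d) = %.3f, p = %.4g\n",
                x$persistence$df[2], x$persistence$F, x$persistence$p))
  }
  invisible(x)
}

#' Default pipeline configuration
#'
#' @param ... overrides merged into the defaults.
#' @return config list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    simulate = list(n_cortical = 200L, n_subcortical = 32L, n_networks = 7L,
                    n_per_group = c(VH = 12, nonVH = 12, control = 0),
                    n_timepoints = 101L, tr_seconds = 0.7,
                    p_stay_segregated_vh = 0.995, hub_scale_vh = 0.6,
                    hub_fraction = 0.15, noise_sd = 0.3),
    input = NULL,           # or list(manifest=, atlas=, tr_seconds=)
    window_len = 63L, step = 1L,
    gamma = 1, louvain_iter = 100L,
    pc_bins = 10L, z_bins = 10L, z_range = c(-5, 5), kmeans_restarts = 50L,
    rho = 1, T_horizon = 1, n_steps = 1001L,
    contrast = c("VH", "nonVH"),
    nbs = list(enabled = FALSE, t_threshold = 2.7, n_perm = 5000L),
    maps = list(enabled = FALSE, n_maps = 8L, anchor_rho = -0.35,
                smoothness_length = 0.3, n_perm = 1000L),
    out_dir = NULL
  )
  modifyList(cfg, list(...))
}

#' Run the full pipeline
#'
#' Orchestrates simulate (or load) -> dynamic FC -> states -> temporal
#' metrics -> state topology (and optional NBS) -> control energies -> group
#' statistics -> optional receptor-map spin screen, writing all result
#' tables and a machine-readable run record when `out_dir` is set. Stage
#' failures halt with the stage and subject named; identical config + seed
#' reproduce identical outputs.
#'
#' @param config a config list (see [default_config()]) or path to a YAML
#'   file with the same fields.
#' @return (invisibly) list with `cohort`/`subjects` inputs, `states`,
#'   `metrics`, `energies`, `nodal_IS`, `topology`, `group_stats`,
#'   `contributors`, `hierarchy_rho`, optional `nbs` and `map_screen`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- modifyList(default_config(),
                                                 yaml::read_yaml(config))
  cfg <- modifyList(default_config(), config)
  seed <- as.integer(cfg$seed)

  # ---- inputs ----
  if (!is.null(cfg$input)) {
    for (f in c(cfg$input$manifest, cfg$input$atlas))
      if (!file.exists(f)) stop_invalid("input file does not exist: ", f)
    atlas <- read_atlas(cfg$input$atlas)
    man <- read.delim(cfg$input$manifest, stringsAsFactors = FALSE)
    base <- dirname(cfg$input$manifest)
    paths <- file.path(base, c(man$bold_path, man$sc_path))
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop_invalid("missing subject files: ", paste(missing, collapse = ", "))
    subjects <- lapply(seq_len(nrow(man)), function(k) list(
      subject_id = man$subject_id[k], group = man$group[k],
      bold = read_bold_tsv(file.path(base, man$bold_path[k]),
                           tr_seconds = cfg$input$tr_seconds %||% NA_real_),
      sc = read_connectome_tsv(file.path(base, man$sc_path[k]))))
    cohort <- NULL
  } else {
    atlas <- make_atlas(cfg$simulate$n_cortical, cfg$simulate$n_subcortical,
                        cfg$simulate$n_networks, seed = seed)
    cohort <- make_cohort(atlas = atlas,
                          n_per_group = cfg$simulate$n_per_group,
                          n_timepoints = cfg$simulate$n_timepoints,
                          tr_seconds = cfg$simulate$tr_seconds,
                          window_len = cfg$window_len, step = cfg$step,
                          p_stay_segregated_vh = cfg$simulate$p_stay_segregated_vh,
                          hub_fraction = cfg$simulate$hub_fraction,
                          hub_scale_vh = cfg$simulate$hub_scale_vh,
                          noise_sd = cfg$simulate$noise_sd, seed = seed)
    subjects <- cohort$subjects
  }

  # ---- per-subject stages ----
  states <- list(); metrics <- list(); energies <- list()
  nodal_IS <- list(); topo <- list(); smfs <- list()
  for (k in seq_along(subjects)) {
    s <- subjects[[k]]
    st <- tryCatch(
      subject_states(s$bold, cfg$window_len, cfg$step, cfg$gamma,
                     cfg$louvain_iter, cfg$pc_bins, cfg$z_bins, cfg$z_range,
                     cfg$kmeans_restarts, seed = derive_seed(seed, 1000L + k)),
      error = function(e) stop_invalid(sprintf(
        "stage 'states' failed for subject %s: %s", s$subject_id,
        conditionMessage(e))))
    states[[s$subject_id]] <- st$assignment
    metrics[[k]] <- cbind(data.frame(subject_id = s$subject_id,
                                     group = s$group), st$metrics)
    en <- tryCatch(
      subject_energies(s$sc, st$dfc, st$assignment, cfg$rho, cfg$T_horizon,
                       cfg$n_steps),
      error = function(e) stop_invalid(sprintf(
        "stage 'control' failed for subject %s: %s", s$subject_id,
        conditionMessage(e))))
    if (!is.null(en)) {
      le <- en$suite$log_energy
      energies[[k]] <- data.frame(subject_id = s$subject_id, group = s$group,
                                  log_IS = le[["IS"]], log_SI = le[["SI"]],
                                  log_II = le[["II"]], log_SS = le[["SS"]])
      nodal_IS[[s$subject_id]] <- en$suite$nodal_energy["IS", ]
      smfs[[s$subject_id]] <- en$state_mean
      topo[[k]] <- data.frame(
        subject_id = s$subject_id, group = s$group,
        density_I = fc_density(en$state_mean$Integrated),
        density_S = fc_density(en$state_mean$Segregated),
        entropy_I = weight_entropy(en$state_mean$Integrated),
        entropy_S = weight_entropy(en$state_mean$Segregated),
        sfc_I = structure_function_coupling(s$sc, en$state_mean$Integrated),
        sfc_S = structure_function_coupling(s$sc, en$state_mean$Segregated))
    }
  }
  metrics <- do.call(rbind, metrics)
  energies <- if (length(energies)) do.call(rbind, energies) else NULL
  topo <- if (length(topo)) do.call(rbind, topo) else NULL
  nodal_mat <- if (length(nodal_IS)) do.call(rbind, nodal_IS) else NULL
  if (!is.null(nodal_mat)) colnames(nodal_mat) <- atlas$parcel_id

  gs <- group_stats(metrics, energies, contrast = cfg$contrast)
  contributors <- if (!is.null(nodal_mat)) nodal_contributions(nodal_mat) else NULL
  hierarchy_rho <- if (!is.null(contributors))
    hierarchy_correlation(contributors$mean_log_energy, atlas) else NULL

  nbs_res <- NULL
  if (isTRUE(cfg$nbs$enabled) && length(smfs) >= 4) {
    grp <- metrics$group[match(names(smfs), metrics$subject_id)]
    keep <- grp %in% cfg$contrast
    nbs_res <- lapply(c("Integrated", "Segregated"), function(st)
      nbs(lapply(smfs[keep], `[[`, st), grp[keep],
          t_threshold = cfg$nbs$t_threshold, n_perm = cfg$nbs$n_perm,
          seed = derive_seed(seed, 77L)))
    names(nbs_res) <- c("Integrated", "Segregated")
  }

  map_screen <- NULL
  if (isTRUE(cfg$maps$enabled) && !is.null(contributors)) {
    emap <- contributors$mean_log_energy
    maps <- list()
    for (m in seq_len(cfg$maps$n_maps)) {
      maps[[sprintf("receptor_%02d", m)]] <- make_receptor_map(
        atlas, smoothness_length = cfg$maps$smoothness_length,
        anchor_map = if (m == 1L) emap else NULL,
        anchor_rho = cfg$maps$anchor_rho,
        seed = derive_seed(seed, 500L + m))
    }
    map_screen <- map_family_screen(emap, maps, atlas,
                                    n_perm = cfg$maps$n_perm,
                                    seed = derive_seed(seed, 88L))
  }

  out <- list(atlas = atlas, cohort = cohort, states = states,
              metrics = metrics, energies = energies, topology = topo,
              nodal_IS = nodal_mat, group_stats = gs,
              contributors = contributors, hierarchy_rho = hierarchy_rho,
              nbs = nbs_res, map_screen = map_screen, config = cfg)

  if (!is.null(cfg$out_dir)) write_run(out, cfg)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_run <- function(out, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) if (!is.null(df))
    write.table(df, file.path(cfg$out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(out$metrics, "temporal_metrics.tsv")
  wt(out$energies, "energies.tsv")
  wt(out$topology, "state_topology.tsv")
  wt(out$map_screen, "map_screen.tsv")
  if (!is.null(out$nodal_IS))
    wt(data.frame(parcel_id = colnames(out$nodal_IS), t(out$nodal_IS),
                  check.names = FALSE), "nodal_energy_IS.tsv")
  labels <- do.call(rbind, lapply(names(out$states), function(sid)
    data.frame(subject_id = sid,
               window_index = seq_along(out$states[[sid]]$labels),
               state = out$states[[sid]]$labels)))
  wt(labels, "state_labels.tsv")
  if (!is.null(out$contributors)) {
    atlas <- out$atlas
    top <- out$contributors$top
    wt(data.frame(parcel_id = atlas$parcel_id[top],
                  network = atlas$network[top],
                  mean_log_energy = out$contributors$mean_log_energy[top]),
       "top_contributors.tsv")
  }
  record <- list(package_version = as.character(utils::packageVersion("dynstates")),
                 r_version = R.version.string,
                 config = cfg[setdiff(names(cfg), "out_dir")],
                 hierarchy_rho = out$hierarchy_rho)
  jsonlite::write_json(record, file.path(cfg$out_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(NULL)
}
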