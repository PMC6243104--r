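# End-to-end orchestration: featurize -> tICA -> KDE/modes -> k-medoids ->
# ITS scan -> micro MSM -> PCCA+ -> macro MSM -> centroids -> structural
# summaries -> external projections, all driven by one config and one seed,
# with every artifact written to a run directory listed in a manifest.

#' Build an analysis configuration
#'
#' Defaults reproduce the canonical loop-dynamics protocol: tICA at a 5 ns
#' lag with 16 retained components, k-medoids microstates (32 clusters; use
#' 16 for a simpler loop), a reversible microstate MSM at an 8 ns lag
#' chosen by implied-timescale convergence, PCCA+ macrostates with the
#' macrostate model estimated at an independent 115 ns lag, hydrogen bonds
#' at 3.2 A / 20 deg, and Shrake-Rupley SASA with a 1.4 A probe. All lag
#' values are in ns and converted once through `frame_interval`.
#'
#' @param input Either `list(type = "synthetic", spec = <synthetic_spec>)`
#'   or `list(type = "trajectories", paths, topology, frame_interval)`.
#' @param selection Residue-range text for the loop (ignored for synthetic
#'   input, which carries its own angle list).
#' @param seed Single seed governing every stochastic stage.
#' @param ... Overrides for any default listed below.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(input, selection = NULL, seed = 2018, ...) {
  cfg <- list(
    input = input,
    selection = selection,
    embed = "sincos",
    tica_lag_ns = 5,
    n_components = 16,
    n_clusters = 32,
    its_lags_ns = c(1, 2, 3, 4, 5, 6, 8, 10, 12, 16, 20),
    its_n_timescales = 5,
    its_tolerance = 0.10,
    its_n_slow = 3,
    micro_lag_ns = 8,
    macro_lag_ns = 115,
    n_macrostates = "auto",
    kde_grid = 128,
    mode_prominence = 0.05,
    hbond_dist = 3.2,
    hbond_angle = 20,
    sasa_probe = 1.4,
    sasa_points = 960,
    external_pdbs = character(0),
    max_cluster_frames = 20000,
    max_kde_samples = 20000,
    centroid_max_members = 5000,
    reversible = TRUE,
    seed = as.integer(seed)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")), "config_error")
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "analysis_config")
}

#' Write / read an analysis configuration (JSON)
#'
#' The config round-trips unchanged (synthetic specs included), so a run
#' can be reproduced from its persisted config alone.
#'
#' @param config An `analysis_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  obj <- unclass(config)
  if (identical(obj$input$type, "synthetic")) {
    sp <- unclass(obj$input$spec)
    sp$T_true <- as.data.frame(sp$T_true)
    sp$means <- as.data.frame(sp$means)
    obj$input$spec <- sp
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$input$type, "synthetic")) {
    sp <- obj$input$spec
    obj$input$spec <- synthetic_spec(
      T_true = as.matrix(sp$T_true), means = as.matrix(sp$means),
      kappa = sp$kappa, n_trajectories = sp$n_trajectories,
      n_frames = sp$n_frames, frame_interval = sp$frame_interval,
      seed = sp$seed, info = as.data.frame(sp$info)
    )
  }
  if (!is.null(obj$external_pdbs) && length(obj$external_pdbs) == 0) {
    obj$external_pdbs <- character(0)
  }
  structure(obj, class = "analysis_config")
}

pipeline_stage <- function(name, log_con, code) {
  msg <- sprintf("[%s] stage %s", format(Sys.time(), "%H:%M:%S"), name)
  message(msg)
  if (!is.null(log_con)) writeLines(msg, log_con)
  tryCatch(code, error = function(e) {
    abort(sprintf("stage '%s' failed: %s (partial artifacts retained)",
                  name, conditionMessage(e)), "stage_error")
  })
}

#' Run the full loop-dynamics analysis pipeline
#'
#' Executes every stage from featurization to macrostate characterization
#' and writes all tables, model archives and a machine-readable manifest
#' under `outdir`. Numeric outputs are fully determined by the config and
#' its seed: re-running with the same config yields byte-identical tables.
#'
#' For synthetic input the true hidden labels are known, so the manifest
#' additionally reports recovery statistics (adjusted Rand index against
#' the hidden states, L1 error of the macrostate stationary distribution).
#' Structural summaries require Cartesian input and are skipped for
#' dihedral-only synthetic data.
#'
#' If the implied timescales do not converge, or no slow processes separate
#' from the fast ones, the macrostate stages are skipped and the manifest
#' records the non-convergence status instead (the honest outcome for a
#' loop whose slowest motions exceed the sampled timescales).
#'
#' @param config An `analysis_config`.
#' @param outdir Run directory (created; existing files overwritten).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  manifest <- list(package_version = as.character(utils::packageVersion("loopmsm")),
                   seed = config$seed, files = list(), status = list())
  write_config(config, file.path(outdir, "config.json"))
  manifest$files$config <- "config.json"

  hidden <- NULL; ensemble <- NULL; selection <- NULL
  series <- pipeline_stage("featurize", log_con, {
    if (identical(config$input$type, "synthetic")) {
      gen <- generate_hmm_trajectories(config$input$spec)
      hidden <- gen$hidden
      gen$series
    } else {
      ensemble <- load_ensemble(config$input$paths, config$input$topology,
                                 config$input$frame_interval)
      selection <- select_loop(ensemble, config$selection)
      backbone_dihedrals(ensemble, selection)
    }
  })
  fi <- series$frame_interval
  fm <- circular_embed(series, mode = config$embed)

  tica <- pipeline_stage("tica", log_con, {
    m <- estimate_tica(fm, lag = config$tica_lag_ns, lag_unit = "ns",
                       n_components = config$n_components)
    save_tica(m, file.path(outdir, "tica_model.json"))
    m
  })
  manifest$files$tica_model <- "tica_model.json"
  proj <- tica_project(tica, fm)
  pipeline_stage("project", log_con, {
    st <- stack_trajectories(proj$data)
    keep <- min(4L, proj$k)
    df <- cbind(st$ids, as.data.frame(st$X[, seq_len(keep), drop = FALSE]))
    names(df)[-(1:2)] <- paste0("tic", seq_len(keep))
    write_table(df, file.path(outdir, "projections.csv"))
  })
  manifest$files$projections <- "projections.csv"

  pipeline_stage("density", log_con, {
    g2 <- kde_density(proj, dims = c(1, 2), grid_size = config$kde_grid,
                      n_max = config$max_kde_samples)
    export_grid(g2, file.path(outdir, "kde_tic12"))
    modes <- find_modes(g2, config$mode_prominence)
    write_table(modes, file.path(outdir, "modes_tic12.csv"))
    manifest$status$n_modes_tic12 <- nrow(modes)
    for (d in seq_len(min(8, proj$k))) {
      g1 <- kde_density(proj, dims = d, grid_size = config$kde_grid,
                        n_max = config$max_kde_samples)
      utils::write.csv(data.frame(coord = g1$axes[[1]], density = g1$values),
                       file.path(outdir, sprintf("kde_tic%d.csv", d)), row.names = FALSE)
    }
  })
  manifest$files$kde <- "kde_tic12_density.csv"
  manifest$files$modes <- "modes_tic12.csv"

  clustering <- pipeline_stage("cluster", log_con, {
    st <- stack_trajectories(proj$data)
    n <- nrow(st$X)
    sub <- seq_len(n)
    if (n > config$max_cluster_frames) {
      sub <- unique(round(seq(1, n, length.out = config$max_cluster_frames)))
    }
    cl <- kmedoids(st$X[sub, , drop = FALSE], config$n_clusters, seed = config$seed)
    cl$medoid_id <- st$ids[sub[cl$medoid_index], , drop = FALSE]
    cl$subsample <- sub
    cl
  })
  labels <- assign_clusters(clustering, proj)
  export_labels(labels, file.path(outdir, "microstates.csv"))
  manifest$files$microstates <- "microstates.csv"

  its <- pipeline_stage("its", log_con, {
    lags <- vapply(config$its_lags_ns, ns_to_frames, integer(1), frame_interval = fi)
    t <- implied_timescales(labels, lags, n_timescales = config$its_n_timescales,
                            reversible = config$reversible, frame_interval = fi)
    export_its(t, file.path(outdir, "implied_timescales.csv"))
    t
  })
  manifest$files$its <- "implied_timescales.csv"
  lag_sel <- select_lag(its, tolerance = config$its_tolerance,
                        n_slow = config$its_n_slow)
  manifest$status$lag_selection <- lag_sel

  if (!lag_sel$converged) {
    manifest$status$macrostates <- "skipped: implied timescales not converged"
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, na = "null")
    return(invisible(manifest))
  }

  micro_lag <- if (identical(config$micro_lag_ns, "auto")) lag_sel$lag_frames
               else ns_to_frames(config$micro_lag_ns, fi)
  micro <- pipeline_stage("micro_msm", log_con, {
    mle_transition_matrix(count_transitions(labels, micro_lag),
                          reversible = config$reversible, frame_interval = fi)
  })
  manifest$status$micro <- list(lag_frames = micro_lag,
                                n_active = length(micro$active),
                                fraction_trimmed = micro$fraction_trimmed)

  # a relaxation timescale below the lag it was estimated at is unresolved
  # noise; without at least two resolved slow processes there is nothing to
  # coarse-grain into metastable states
  finite_ts <- micro$implied_timescales_frames[is.finite(micro$implied_timescales_frames)]
  if (length(finite_ts) < 2 || max(finite_ts) < micro_lag) {
    manifest$status$macrostates <- "skipped: no slow process resolved above the microstate lag"
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, na = "null")
    return(invisible(manifest))
  }

  m_choice <- pipeline_stage("macrostate_count", log_con, {
    if (identical(config$n_macrostates, "auto")) {
      choose_macrostate_count(its[its$lag_frames == micro_lag, , drop = FALSE])
    } else {
      list(m = as.integer(config$n_macrostates), gap_ratio = NA_real_,
           low_confidence = FALSE)
    }
  })
  manifest$status$n_macrostates <- m_choice$m
  manifest$status$macrostate_gap_ratio <- m_choice$gap_ratio
  manifest$status$macrostate_low_confidence <- m_choice$low_confidence

  macro <- pipeline_stage("pcca", log_con, pcca_plus(micro, m_choice$m))
  mm <- pipeline_stage("macro_msm", log_con, {
    macrostate_msm(labels, macro, lag = ns_to_frames(config$macro_lag_ns, fi),
                   reversible = config$reversible, frame_interval = fi)
  })
  pipeline_stage("macro_export", log_con, {
    write_table(mm$jumps, file.path(outdir, "jump_probabilities.csv"))
    write_table(data.frame(macrostate = mm$model$active,
                           pi_eigen = mm$model$pi,
                           pi_membership = macro$macro_pi_from_chi[mm$model$active]),
                file.path(outdir, "macrostate_populations.csv"))
    write_table(data.frame(microstate = micro$active,
                           macrostate = macro$crisp,
                           as.data.frame(macro$chi) |>
                             stats::setNames(paste0("chi", seq_len(macro$m)))),
                file.path(outdir, "memberships.csv"))
    utils::write.csv(as.data.frame(mm$model$T),
                     file.path(outdir, "macro_transition_matrix.csv"), row.names = FALSE)
  })
  manifest$files$jumps <- "jump_probabilities.csv"
  manifest$files$populations <- "macrostate_populations.csv"
  manifest$files$memberships <- "memberships.csv"
  manifest$files$macro_T <- "macro_transition_matrix.csv"
  manifest$status$metastability <- mm$metastability

  centroids <- pipeline_stage("centroids", log_con, {
    st <- stack_trajectories(proj$data)
    mlab <- unlist(mm$labels, use.names = FALSE)
    rows <- list()
    for (s in sort(unique(mlab[!is.na(mlab)]))) {
      memb <- which(mlab == s)
      cen <- cluster_centroid(st$X[memb, , drop = FALSE], st$ids[memb, , drop = FALSE],
                              n_max = config$centroid_max_members)
      rows[[length(rows) + 1]] <- data.frame(state = s, cen$id)
    }
    df <- do.call(rbind, rows)
    write_table(df, file.path(outdir, "centroids.csv"))
    df
  })
  manifest$files$centroids <- "centroids.csv"

  if (!is.null(ensemble)) {
    pipeline_stage("structure", log_con, {
      for (i in seq_len(nrow(centroids))) {
        tr <- ensemble$coords[[centroids$trajectory[i]]]
        write_pdb(ensemble$topology,
                  tr[centroids$frame[i], , ],
                  file.path(outdir, sprintf("centroid_state%d.pdb", centroids$state[i])))
      }
      tab <- centroid_dihedral_table(ensemble, centroids, selection)
      write_table(tab, file.path(outdir, "centroid_dihedrals.csv"))
      mlab <- unlist(mm$labels, use.names = FALSE)
      has_h <- any(ensemble$topology$element == "H")
      if (!has_h) {
        manifest$status$hbonds <- "skipped: no hydrogens in topology"
      }
      sasa_rows <- list(); bond_lists <- vector("list", length(mlab))
      fidx <- 0
      for (t in seq_along(ensemble$coords)) {
        tr <- ensemble$coords[[t]]
        for (f in seq_len(dim(tr)[1])) {
          fidx <- fidx + 1
          co <- tr[f, , ]
          if (has_h) {
            bond_lists[[fidx]] <- find_hbonds(co, ensemble$topology,
                                              config$hbond_dist, config$hbond_angle)
          }
          sasa_rows[[fidx]] <- data.frame(
            trajectory = t, frame = f, state = mlab[fidx],
            sasa = shrake_rupley_sasa(co, ensemble$topology, selection,
                                      probe = config$sasa_probe,
                                      n_points = config$sasa_points)$total)
        }
      }
      sasa_df <- do.call(rbind, sasa_rows)
      write_table(sasa_df, file.path(outdir, "sasa_per_frame.csv"))
      agg <- stats::aggregate(sasa ~ state, data = sasa_df[!is.na(sasa_df$state), ], FUN = mean)
      write_table(agg, file.path(outdir, "sasa_per_state.csv"))
      if (has_h) {
        pairs <- unique(do.call(rbind, lapply(bond_lists, function(b)
          b[, c("donor_label", "acceptor_label"), drop = FALSE])))
        occ <- list()
        for (p in seq_len(nrow(pairs))) {
          o <- hbond_occupancy(bond_lists, mlab, pairs$donor_label[p], pairs$acceptor_label[p])
          o$donor <- pairs$donor_label[p]; o$acceptor <- pairs$acceptor_label[p]
          occ[[p]] <- o
        }
        if (length(occ) > 0) {
          write_table(do.call(rbind, occ), file.path(outdir, "hbond_occupancy.csv"))
        }
      }
    })
    manifest$files$sasa <- "sasa_per_state.csv"
    manifest$files$centroid_dihedrals <- "centroid_dihedrals.csv"
  } else {
    manifest$status$structure <- "skipped: synthetic dihedral input has no Cartesian coordinates"
  }

  if (length(config$external_pdbs) > 0) {
    pipeline_stage("external", log_con, {
      rows <- lapply(config$external_pdbs, function(p) {
        xy <- project_external(tica, p, config$selection,
                               mode = config$embed, training_info = series$info)
        data.frame(structure = basename(p), tic1 = xy[1, 1], tic2 = xy[1, 2])
      })
      write_table(do.call(rbind, rows), file.path(outdir, "external_projections.csv"))
    })
    manifest$files$external <- "external_projections.csv"
  }

  if (!is.null(hidden)) {
    mlab <- unlist(mm$labels, use.names = FALSE)
    hid <- unlist(hidden, use.names = FALSE)
    ok <- !is.na(mlab)
    pi_true <- stationary_distribution(config$input$spec$T_true)
    pi_est <- mm$model$pi
    l1 <- best_permutation_l1(pi_est, pi_true)
    manifest$status$recovery <- list(
      ari = adjusted_rand_index(mlab[ok], hid[ok]),
      coarse_pi_l1 = l1
    )
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, na = "null")
  manifest$files$manifest <- "manifest.json"
  invisible(manifest)
}

# Minimum L1 distance between two distributions over all label
# permutations (macrostate numbering is arbitrary).
best_permutation_l1 <- function(p, q) {
  if (length(p) != length(q)) return(NA_real_)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(x) c(v[i], x))
    }))
  }
  min(vapply(perms(seq_along(p)), function(pm) sum(abs(p[pm] - q)), numeric(1)))
}

#' Render report figures from a completed run directory
#'
#' Figures are views of the persisted tables only (never of in-memory
#' state): 1-D marginal densities of the leading tICs, the 2-D tIC1-tIC2
#' density with centroid and external-structure overlays, and the
#' macrostate network with arrow widths proportional to jump probability
#' (widths also written to a sidecar CSV). Missing artifacts are listed
#' and skipped.
#'
#' @param outdir A run directory produced by [run_pipeline()].
#' @param format `"pdf"` (default; always available) or `"png"`.
#' @return Character vector of figure paths.
#' @export
render_reports <- function(outdir, format = c("pdf", "png")) {
  format <- match.arg(format)
  open_dev <- function(path) {
    if (format == "pdf") grDevices::pdf(path, width = 7, height = 6)
    else grDevices::png(path, width = 700, height = 600)
  }
  figs <- character(0); skipped <- character(0)
  p <- function(...) file.path(outdir, ...)

  marg <- Sys.glob(p("kde_tic[0-9].csv"))
  if (length(marg) > 0) {
    f <- p(paste0("fig_marginals.", format))
    open_dev(f)
    graphics::par(mfrow = c(2, ceiling(length(marg) / 2)), mar = c(4, 4, 2, 1))
    for (m in marg) {
      d <- utils::read.csv(m)
      graphics::plot(d$coord, d$density, type = "l",
                     xlab = sub("kde_(tic[0-9]+)\\.csv", "\\1", basename(m)),
                     ylab = "density")
    }
    grDevices::dev.off()
    figs <- c(figs, f)
  } else skipped <- c(skipped, "kde_tic*.csv")

  if (file.exists(p("kde_tic12_density.csv"))) {
    f <- p(paste0("fig_landscape.", format))
    z <- as.matrix(utils::read.csv(p("kde_tic12_density.csv")))
    a1 <- utils::read.csv(p("kde_tic12_axis1.csv"))$coord
    a2 <- utils::read.csv(p("kde_tic12_axis2.csv"))$coord
    open_dev(f)
    graphics::image(a1, a2, z, col = grDevices::hcl.colors(64, "YlGnBu", rev = TRUE),
                    xlab = "tIC1", ylab = "tIC2", main = "projected density")
    if (file.exists(p("centroids.csv")) && file.exists(p("projections.csv"))) {
      cen <- utils::read.csv(p("centroids.csv"))
      pr <- utils::read.csv(p("projections.csv"))
      key <- paste(pr$trajectory, pr$frame)
      hit <- match(paste(cen$trajectory, cen$frame), key)
      graphics::points(pr$tic1[hit], pr$tic2[hit], pch = 21, bg = "white", cex = 1.6)
      graphics::text(pr$tic1[hit], pr$tic2[hit], labels = cen$state, cex = 0.7)
    }
    if (file.exists(p("external_projections.csv"))) {
      ex <- utils::read.csv(p("external_projections.csv"))
      graphics::points(ex$tic1, ex$tic2, pch = 4, lwd = 2, col = "red")
    }
    grDevices::dev.off()
    figs <- c(figs, f)
  } else skipped <- c(skipped, "kde_tic12_density.csv")

  if (file.exists(p("jump_probabilities.csv")) && file.exists(p("macrostate_populations.csv"))) {
    f <- p(paste0("fig_macrostates.", format))
    j <- utils::read.csv(p("jump_probabilities.csv"))
    pop <- utils::read.csv(p("macrostate_populations.csv"))
    m <- nrow(pop)
    ang <- 2 * pi * (seq_len(m) - 1) / m
    xy <- cbind(cos(ang), sin(ang))
    scale <- 8 / max(j$probability)
    j$width <- j$probability * scale
    write_table(j, p("fig_macrostates_arrows.csv"))
    open_dev(f)
    graphics::plot(xy, xlim = c(-1.5, 1.5), ylim = c(-1.5, 1.5), asp = 1,
                   xlab = "", ylab = "", axes = FALSE, type = "n",
                   main = "macrostate jump probabilities")
    for (i in seq_len(nrow(j))) {
      a <- xy[match(j$from[i], pop$macrostate), ]
      b <- xy[match(j$to[i], pop$macrostate), ]
      off <- (b - a) * 0.18
      graphics::arrows(a[1] + off[1], a[2] + off[2], b[1] - off[1], b[2] - off[2],
                       lwd = pmax(0.2, j$width[i]), length = 0.1, col = "grey30")
    }
    graphics::symbols(xy[, 1], xy[, 2], circles = 0.12 + 0.25 * pop$pi_eigen,
                      inches = FALSE, add = TRUE, bg = "lightsteelblue")
    graphics::text(xy[, 1], xy[, 2],
                   labels = sprintf("%d\n%.2f", pop$macrostate, pop$pi_eigen), cex = 0.8)
    grDevices::dev.off()
    figs <- c(figs, f)
  } else skipped <- c(skipped, "jump_probabilities.csv")

  if (file.exists(p("centroid_dihedrals.csv"))) {
    f <- p(paste0("fig_centroid_dihedrals.", format))
    d <- utils::read.csv(p("centroid_dihedrals.csv"))
    open_dev(f)
    graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    for (an in c("phi", "psi")) {
      dd <- d[d$angle == an, ]
      graphics::plot(range(dd$resid), c(-180, 180), type = "n",
                     xlab = "residue", ylab = sprintf("%s (deg)", an))
      for (s in unique(dd$state)) {
        ds <- dd[dd$state == s, ]
        graphics::lines(ds$resid, ds$value_deg, type = "b", pch = 19,
                        col = s + 1)
      }
      graphics::legend("topright", legend = unique(dd$state), col = unique(dd$state) + 1,
                       pch = 19, cex = 0.7, title = "state")
    }
    grDevices::dev.off()
    figs <- c(figs, f)
  }
  if (length(skipped) > 0) {
    message("skipped (missing artifacts): ", paste(skipped, collapse = ", "))
  }
  figs
}
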