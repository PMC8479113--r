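#' Configuration for a two-state comparison run
#'
#' Collects every knob of the pipeline with its default, so a run is fully
#' self-describing; the configuration is echoed verbatim into the run
#' metadata. States may be given as [synthetic_spec()]s (generated on the
#' fly) or as paths to multi-model PDB files.
#'
#' @param state_a,state_b specs or file paths for the two states.
#' @param analyses analysis stages to run (default all).
#' @param seed global seed, propagated to every stochastic stage.
#' @param outdir output directory (created if needed).
#' @param params named list of per-stage parameter overrides; see Details.
#'
#' @details Recognized `params` entries (with defaults): `core_fraction`
#'   (0.7), `pca_k` (10), `probe` (1.4), `sasa_points` (480),
#'   `sasa_frames` (12), `iasa_frames` (12), `pocket_spacing` (0.8),
#'   `pocket_frames` (25), `tunnel_spacing` (0.8), `tunnel_frames` (3),
#'   `tunnel_probe` (1.0), `cvae_epochs` (40), `cvae_latent` (7),
#'   `cvae_frames` (150 per state).
#' @return a list of class `hxd_config`.
#' @export
pipeline_config <- function(state_a = hexamer_state_spec("deoxy"),
                            state_b = hexamer_state_spec("oxy"),
                            analyses = c("rmsd", "rmsf", "rg", "dccm", "pca",
                                         "sasa", "iasa", "pockets",
                                         "tunnels", "cvae"),
                            seed = 1L, outdir = tempfile("hexadyn_run_"),
                            params = list()) {
  defaults <- list(core_fraction = 0.7, pca_k = 10L, probe = 1.4,
                   sasa_points = 480L, sasa_frames = 12L, iasa_frames = 12L,
                   pocket_spacing = 0.8, pocket_frames = 25L,
                   tunnel_spacing = 0.8, tunnel_frames = 3L,
                   tunnel_probe = 1.0, cvae_epochs = 40L, cvae_latent = 7L,
                   cvae_frames = 150L)
  defaults[names(params)] <- params
  structure(list(state_a = state_a, state_b = state_b,
                 analyses = analyses, seed = as.integer(seed),
                 outdir = outdir, params = defaults),
            class = "hxd_config")
}

.load_state <- function(x, seed) {
  if (inherits(x, "hxd_synth_spec")) {
    x$seed <- x$seed + seed
    generate_hexamer_trajectory(x)
  } else if (is.character(x)) read_trajectory(x)
  else if (inherits(x, "hxd_trajectory")) x
  else stop("state must be a spec, a trajectory, or a PDB path")
}

.sub_frames <- function(nf, k) unique(round(seq(1, nf, length.out = min(k, nf))))

#' Run the full two-state comparison pipeline
#'
#' Executes the requested stages in dependency order on the two state
#' trajectories, writes every intermediate table under the configured
#' output directory, and returns a report. A failing stage is recorded in
#' the report and its dependents are skipped; the report is still emitted.
#'
#' @param config an [pipeline_config()].
#' @return object of class `hxd_report`; sections named after the stages,
#'   each with the key numbers and the files written, or an `error`
#'   message, or `skipped = TRUE`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "hxd_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  report <- list()
  log <- function(stage, value) report[[stage]] <<- value
  stage <- function(name, fun) {
    if (!(name %in% config$analyses)) {
      report[[name]] <<- list(skipped = TRUE)
      return(invisible(NULL))
    }
    report[[name]] <<- tryCatch(fun(), error = function(e)
      list(error = conditionMessage(e)))
    invisible(NULL)
  }
  ta <- .load_state(config$state_a, config$seed)
  tb <- .load_state(config$state_b, config$seed)
  ca <- atom_select(ta, name = "CA"); cb <- atom_select(tb, name = "CA")
  out <- function(f) file.path(config$outdir, f)

  stage("rmsd", function() {
    ra <- conventional_rmsd(ta, atoms = ca)
    rb <- conventional_rmsd(tb, atoms = cb)
    core_a <- core_align(ta, fraction = p$core_fraction, atoms = ca)
    core_b <- core_align(tb, fraction = p$core_fraction, atoms = cb)
    utils::write.csv(data.frame(frame = seq_along(ra), state_a = ra,
                                state_b = rb), out("rmsd.csv"),
                     row.names = FALSE)
    list(mean_a = mean(ra), mean_b = mean(rb),
         core_mean_a = mean(core_a$core_rmsd),
         core_mean_b = mean(core_b$core_rmsd),
         files = "rmsd.csv")
  })
  stage("rmsf", function() {
    fa <- rmsf(ta, atoms = ca); fb <- rmsf(tb, atoms = cb)
    utils::write.csv(data.frame(atom = seq_along(fa), state_a = fa,
                                state_b = fb), out("rmsf.csv"),
                     row.names = FALSE)
    list(mean_a = mean(fa), mean_b = mean(fb), files = "rmsf.csv")
  })
  stage("rg", function() {
    ga <- radius_of_gyration(ta, atoms = ca)
    gb <- radius_of_gyration(tb, atoms = cb)
    utils::write.csv(data.frame(frame = seq_along(ga), state_a = ga,
                                state_b = gb), out("rg.csv"),
                     row.names = FALSE)
    list(mean_a = mean(ga), mean_b = mean(gb), files = "rg.csv")
  })
  stage("dccm", function() {
    ma <- compute_dccm(ta, atoms = ca); mb <- compute_dccm(tb, atoms = cb)
    write_matrix_csv(ma$values, out("dccm_a.csv"))
    write_matrix_csv(mb$values, out("dccm_b.csv"))
    chains <- split(seq_along(ca), ta$topology$chain_id[ca])
    ba <- dccm_block_summary(ma, chains)
    bb <- dccm_block_summary(mb, chains)
    write_matrix_csv(ba, out("dccm_blocks_a.csv"))
    write_matrix_csv(bb, out("dccm_blocks_b.csv"))
    list(block_a = ba, block_b = bb,
         files = c("dccm_a.csv", "dccm_b.csv",
                   "dccm_blocks_a.csv", "dccm_blocks_b.csv"))
  })
  stage("pca", function() {
    pa <- fit_pca(ta, atoms = ca); pb <- fit_pca(tb, atoms = cb)
    cmp <- compare_subspaces(pa, pb, k = p$pca_k)
    utils::write.csv(data.frame(mode = seq_along(pa$values),
                                state_a = pa$values, state_b = pb$values),
                     out("eigenvalues.csv"), row.names = FALSE)
    write_matrix_csv(cmp$dot_matrix, out("dot_matrix.csv"))
    list(var1_a = pa$values[1] / sum(pa$values),
         var1_b = pb$values[1] / sum(pb$values),
         rmsip = cmp$rmsip, overlap_pct = cmp$overlap_pct,
         average_max_dot = cmp$average_max_dot,
         files = c("eigenvalues.csv", "dot_matrix.csv"))
  })
  stage("sasa", function() {
    fa <- .sub_frames(n_frames(ta), p$sasa_frames)
    sa <- sasa_series(ta, probe = p$probe, n_points = p$sasa_points,
                      frames = fa)
    sb <- sasa_series(tb, probe = p$probe, n_points = p$sasa_points,
                      frames = .sub_frames(n_frames(tb), p$sasa_frames))
    utils::write.csv(sa, out("sasa_a.csv"), row.names = FALSE)
    utils::write.csv(sb, out("sasa_b.csv"), row.names = FALSE)
    list(mean_total_a = mean(sa$total), mean_total_b = mean(sb$total),
         mean_subunit_a = mean(sa$subunit_mean),
         mean_subunit_b = mean(sb$subunit_mean),
         files = c("sasa_a.csv", "sasa_b.csv"))
  })
  stage("iasa", function() {
    ga_top <- unique(ta$topology$chain_id[ta$topology$ring == "top"])
    ga_bot <- unique(ta$topology$chain_id[ta$topology$ring == "bottom"])
    ia <- iasa(ta, ga_top, ga_bot, probe = p$probe,
               n_points = p$sasa_points,
               frames = .sub_frames(n_frames(ta), p$iasa_frames))
    ib <- iasa(tb, ga_top, ga_bot, probe = p$probe,
               n_points = p$sasa_points,
               frames = .sub_frames(n_frames(tb), p$iasa_frames))
    utils::write.csv(ia, out("iasa_a.csv"), row.names = FALSE)
    utils::write.csv(ib, out("iasa_b.csv"), row.names = FALSE)
    list(mean_a = mean(ia$iasa), mean_b = mean(ib$iasa),
         files = c("iasa_a.csv", "iasa_b.csv"))
  })
  stage("pockets", function() {
    bounds <- cbind(c(-6, -6, -11), c(6, 6, 11))
    ka <- detect_pockets(ta, spacing = p$pocket_spacing,
                         grid_bounds = bounds,
                         frames = .sub_frames(n_frames(ta), p$pocket_frames))
    kb <- detect_pockets(tb, spacing = p$pocket_spacing,
                         grid_bounds = bounds,
                         frames = .sub_frames(n_frames(tb), p$pocket_frames))
    utils::write.csv(pocket_volume_series(ka), out("pockets_a.csv"),
                     row.names = FALSE)
    utils::write.csv(pocket_volume_series(kb), out("pockets_b.csv"),
                     row.names = FALSE)
    list(cumulative_a = ka$cumulative_volume,
         cumulative_b = kb$cumulative_volume,
         mean_a = ka$mean_volume, mean_b = kb$mean_volume,
         files = c("pockets_a.csv", "pockets_b.csv"))
  })
  stage("tunnels", function() {
    start_a <- colMeans(frame_coords(ta, 1L)[
      atom_select(ta, name = c("CU1", "CU2")), , drop = FALSE]) * 0
    run_one <- function(tt, tag) {
      paths <- find_tunnels(tt, start_point = c(0, 0, 0),
                            probe_radius = p$tunnel_probe,
                            spacing = p$tunnel_spacing,
                            frames = .sub_frames(n_frames(tt),
                                                 p$tunnel_frames))
      if (!length(paths)) return(NULL)
      cl <- cluster_tunnels(paths)
      sm <- tunnel_summary(cl)
      utils::write.csv(sm, out(paste0("tunnels_", tag, ".csv")),
                       row.names = FALSE)
      lin <- lining_residues(cl[[1]], tt)
      utils::write.csv(lin, out(paste0("tunnel_lining_", tag, ".csv")),
                       row.names = FALSE)
      list(summary = sm, clusters = cl)
    }
    ra <- run_one(ta, "a"); rb <- run_one(tb, "b")
    list(summary_a = ra$summary, summary_b = rb$summary,
         max_bottleneck_a = if (!is.null(ra)) max(ra$summary$max_bottleneck),
         max_bottleneck_b = if (!is.null(rb)) max(rb$summary$max_bottleneck),
         files = c("tunnels_a.csv", "tunnels_b.csv"))
  })
  stage("cvae", function() {
    sa <- config$state_a; sb <- config$state_b
    if (!inherits(sa, "hxd_synth_spec") || !inherits(sb, "hxd_synth_spec"))
      stop("cvae stage needs synthetic state specs")
    sa$seed <- sa$seed + config$seed
    sb$seed <- sb$seed + config$seed + 1000L
    ds <- generate_site_distance_dataset(sa, sb,
                                         frames_per_state = p$cvae_frames,
                                         seed = config$seed)
    m <- train_cvae(ds, latent_dim = p$cvae_latent, epochs = p$cvae_epochs,
                    seed = config$seed)
    emb <- embed_frames(m, ds, projection = "linear")
    utils::write.csv(m$loss, out("cvae_loss.csv"), row.names = FALSE)
    utils::write.csv(emb$data, out("cvae_embedding.csv"), row.names = FALSE)
    list(final_val_loss = m$loss$val[nrow(m$loss)],
         first_val_loss = m$loss$val[1],
         silhouette = latent_silhouette(emb),
         files = c("cvae_loss.csv", "cvae_embedding.csv"))
  })
  write_run_metadata(list(
    analyses = config$analyses, seed = config$seed,
    params = p, timestamp = as.character(Sys.time()),
    package_version = as.character(utils::packageVersion("hexadyn"))),
    file.path(config$outdir, "run_metadata.json"))
  structure(list(sections = report, outdir = config$outdir,
                 seed = config$seed),
            class = "hxd_report")
}

#' @export
print.hxd_report <- function(x, ...) {
  cat("<hxd_report>", x$outdir, "\n")
  for (nm in names(x$sections)) {
    s <- x$sections[[nm]]
    status <- if (isTRUE(s$skipped)) "skipped"
      else if (!is.null(s$error)) paste("ERROR:", s$error) else "ok"
    cat(sprintf("  %-8s %s\n", nm, status))
  }
  invisible(x)
}

#' Write the bundled synthetic fixture set
#'
#' Writes the default open ("deoxy") and closed ("oxy") synthetic
#' trajectories as multi-model PDB, the toy oracle geometries as PDB plus
#' JSON ground-truth sidecars, and a checksummed manifest. Regeneration
#' with the same seed reproduces the checksums.
#'
#' @param dir output directory.
#' @param seed generator seed.
#' @param n_frames frames per state trajectory.
#' @return path of the manifest file, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1L, n_frames = 60L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "open_deoxy.pdb")
  fb <- file.path(dir, "closed_oxy.pdb")
  write_trajectory(generate_hexamer_trajectory(
    hexamer_state_spec("deoxy", n_frames = n_frames, seed = seed)), fa)
  write_trajectory(generate_hexamer_trajectory(
    hexamer_state_spec("oxy", n_frames = n_frames, seed = seed + 1L)), fb)
  toys <- list(sphere = generate_toy_geometry("sphere"),
               shell = generate_toy_geometry("hollow_shell"),
               channel = generate_toy_geometry("channel"),
               hourglass = generate_toy_geometry("hourglass"))
  files <- c(fa, fb)
  for (nm in names(toys)) {
    fp <- file.path(dir, paste0("toy_", nm, ".pdb"))
    write_trajectory(as_trajectory(toys[[nm]]), fp)
    fj <- file.path(dir, paste0("toy_", nm, ".json"))
    write_run_metadata(toys[[nm]]$truth, fj)
    files <- c(files, fp, fj)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  invisible(mf)
}
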