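#' Run an end-to-end analysis pipeline from a config
#'
#' Executes the requested stages in dependency order from a single
#' validated configuration and writes every output plus a reproducibility
#' manifest (package version, seeds, parameter snapshot, file hashes) to
#' the output directory. Rerunning with the same config reproduces all
#' outputs bit-identically apart from the manifest timestamp.
#'
#' The config is a named list (or the path of a YAML file) with an
#' `outdir`, an optional global `seed`, and any of the stage blocks:
#' \describe{
#'   \item{pose}{[pose_scenario()] arguments plus optional `conf_thresh`
#'     (0.05), `smooth_width` (5), `arena_cm` (20), `jump_conf_thresh`
#'     (0.5), `jump_speed_thresh` (10). Generates a session, corrects,
#'     smooths, calibrates, computes kinematics and detects events.}
#'   \item{photometry}{[photometry_scenario()] arguments plus optional
#'     `bin_s` (10), `prominence_k` (2). Generates a recording, fits the
#'     isosbestic control, computes and bins dF/F, detects transients.}
#'   \item{dose_response}{[gen_dose_response()] arguments. Generates a
#'     table and fits the four-parameter logistic.}
#'   \item{preference}{`times` (see [gen_preference_session()]) plus
#'     optional `target`. Generates an occupancy track and scores it.}
#' }
#'
#' @param config Named list or path to a YAML config file.
#' @return The run manifest, invisibly; all outputs are files under
#'   `outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("outdir", "seed", "pose", "photometry", "dose_response",
             "preference")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$outdir)) stop("config needs an 'outdir'")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L

  manifest <- list(
    package = "opiometrics",
    version = as.character(utils::packageVersion("opiometrics")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    stages = list(),
    outputs = list()
  )
  add_output <- function(name, path) {
    manifest$outputs[[name]] <<- list(
      path = path, md5 = unname(tools::md5sum(path)))
  }
  take <- function(block, keys) block[intersect(names(block), keys)]

  if (!is.null(config$pose)) {
    blk <- config$pose
    sc_args <- take(blk, names(formals(pose_scenario)))
    sc_args$seed <- sc_args$seed %||% seed
    sc <- do.call(pose_scenario, sc_args)
    ses <- gen_pose_session(sc)
    corrected <- correct_coordinates(ses$track,
      conf_thresh = blk$conf_thresh %||% 0.05,
      protect_frames = candidate_jump_frames(ses$track,
        conf_thresh = blk$jump_conf_thresh %||% 0.5))
    smoothed <- smooth_coordinates(corrected,
      width = blk$smooth_width %||% 5)
    calibrated <- calibrate_arena(smoothed,
      arena_cm = blk$arena_cm %||% sc$arena_cm)
    kin <- compute_kinematics(calibrated)
    ev <- event_table(calibrated, kin,
      conf_thresh = blk$jump_conf_thresh %||% 0.5,
      speed_thresh = blk$jump_speed_thresh %||% 10)

    p1 <- file.path(outdir, "pose_corrected.csv")
    write_pose_table(calibrated, p1); add_output("pose_corrected", p1)
    p2 <- file.path(outdir, "kinematics.csv")
    utils::write.csv(as.data.frame(kin), p2, row.names = FALSE)
    add_output("kinematics", p2)
    p3 <- file.path(outdir, "events.json")
    jsonlite::write_json(list(jumps = ev$jumps, immobility = ev$immobility,
                              totals = ev$totals),
                         p3, auto_unbox = TRUE, digits = NA)
    add_output("events", p3)
    manifest$stages$pose <- list(
      completed = TRUE, seed = sc$seed,
      params = list(conf_thresh = blk$conf_thresh %||% 0.05,
                    smooth_width = blk$smooth_width %||% 5,
                    jump_conf_thresh = blk$jump_conf_thresh %||% 0.5,
                    jump_speed_thresh = blk$jump_speed_thresh %||% 10),
      n_frames = n_frames(calibrated),
      jump_count = ev$totals$jump_count)
  }

  if (!is.null(config$photometry)) {
    blk <- config$photometry
    sc_args <- take(blk, names(formals(photometry_scenario)))
    sc_args$seed <- sc_args$seed %||% seed
    sc <- do.call(photometry_scenario, sc_args)
    ses <- gen_photometry_session(sc)
    rec <- compute_dff(fit_isosbestic(ses$recording))
    binned <- bin_dff(rec$dff, rec$t, bin_s = blk$bin_s %||% 10)
    tr <- detect_transients(rec, k = blk$prominence_k %||% 2)

    p1 <- file.path(outdir, "photometry_dff.csv")
    utils::write.csv(data.frame(t = rec$t, f470 = rec$f470,
                                f405 = rec$f405,
                                fitted405 = as.numeric(rec$fitted405),
                                dff = as.numeric(rec$dff)),
                     p1, row.names = FALSE)
    add_output("photometry_dff", p1)
    p2 <- file.path(outdir, "photometry_binned.csv")
    utils::write.csv(binned, p2, row.names = FALSE)
    add_output("photometry_binned", p2)
    p3 <- file.path(outdir, "transients.tsv")
    utils::write.table(as.data.frame(tr), p3, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    add_output("transients", p3)
    manifest$stages$photometry <- list(
      completed = TRUE, seed = sc$seed,
      params = list(bin_s = blk$bin_s %||% 10,
                    prominence_k = blk$prominence_k %||% 2,
                    baseline_s = sc$baseline_s),
      n_transients = nrow(tr))
  }

  if (!is.null(config$dose_response)) {
    blk <- config$dose_response
    gen_args <- take(blk, names(formals(gen_dose_response)))
    gen_args$seed <- gen_args$seed %||% seed
    tab <- do.call(gen_dose_response, gen_args)
    fit <- fit_logistic4(tab, seed = gen_args$seed)
    p1 <- file.path(outdir, "dose_response.csv")
    utils::write.csv(tab, p1, row.names = FALSE)
    add_output("dose_response", p1)
    p2 <- file.path(outdir, "dose_response_fit.json")
    jsonlite::write_json(list(estimates = as.list(fit$estimates),
                              rss = fit$rss, converged = fit$converged),
                         p2, auto_unbox = TRUE, digits = NA)
    add_output("dose_response_fit", p2)
    manifest$stages$dose_response <- list(
      completed = TRUE, seed = gen_args$seed,
      converged = fit$converged,
      ic50 = unname(fit$estimates[["ic50"]]),
      hill = unname(fit$estimates[["hill"]]))
  }

  if (!is.null(config$preference)) {
    blk <- config$preference
    times <- unlist(blk$times)
    occ <- gen_preference_session(times, fps = blk$fps %||% 40,
                                  seed = blk$seed %||% seed)
    target <- blk$target %||% setdiff(unique(occ$compartment),
                                      "corridor")[1L]
    score <- place_preference_score(occ$compartment, target)
    p1 <- file.path(outdir, "occupancy.csv")
    utils::write.csv(occ, p1, row.names = FALSE)
    add_output("occupancy", p1)
    manifest$stages$preference <- list(
      completed = TRUE, target = target, score = score)
  }

  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
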