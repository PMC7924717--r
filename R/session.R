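# Scriptable session runner: the offline equivalent of the browser update
# loop. A pose trajectory replaces live marker tracking; each frame the
# scene is assembled and the enabled observables are evaluated into one row.

session_defaults <- function() {
  list(clash_threshold = 3.0, clash_mode = "center",
       dielectric = 1, p_forward = 0.03,
       populations = c(LYS_N = 0.70, GLU_O = 0.30),
       q_grid = seq(0.01, 0.5, length.out = 50),
       saxs_exp = NULL, contacts = NULL, pcs_center = NULL,
       pcs_probe = NULL, distance_sites = NULL, hbond_sites = NULL,
       linker = NULL, tick_ms = 200,
       d_sat = 8)
}

site_position <- function(scene, mol, site) {
  tab <- scene$table
  row <- tab[tab$molecule == mol & tab$site == site, , drop = FALSE]
  if (!nrow(row)) stop(sprintf("site %s/%d not in scene", mol, site))
  c(row$x[1], row$y[1], row$z[1])
}

default_charged_sites <- function(molecules) {
  ids <- names(molecules)
  if (length(ids) < 2) return(NULL)
  pick <- function(m) {
    mf <- model_frame(m)
    if (any(mf$charge != 0)) which.max(abs(mf$charge)) else 1L
  }
  list(a = list(mol = ids[1], site = pick(molecules[[1]])),
       b = list(mol = ids[2], site = pick(molecules[[2]])))
}

#' Run a molecular scene session over a pose trajectory
#'
#' For every frame of the trajectory the scene is re-assembled from the
#' frame's poses and each enabled observable is evaluated into one row of
#' the output table. Deterministic for a fixed seed. Observables whose
#' preconditions fail in a frame yield `NA` in that row, with a message.
#'
#' @param molecules named list of [mol_structure()] / [bead_model()]
#'   objects; names must match the trajectory's molecule ids.
#' @param trajectory data.frame as from [read_pose_trajectory()].
#' @param observables character subset of `distance`, `electrostatics`,
#'   `clash`, `hbond`, `proton`, `saxs`, `pcs`, `contacts`, `linker`.
#' @param seed RNG seed recorded in the output header.
#' @param anchors named list/vector of anchor site indices per molecule
#'   (default 1).
#' @param options named list overriding [session_defaults()]: interaction
#'   site selections (`distance_sites`, `hbond_sites`), `clash_threshold`,
#'   `p_forward`, `populations`, `q_grid`, `saxs_exp`, `contacts`,
#'   `pcs_center`, `pcs_probe`, `linker` (list `anchor_a = c(mol, site)`,
#'   `anchor_b`, `n_beads`, `spacing`), `tick_ms`.
#' @return object of class `session_result`: data.frame of per-frame rows
#'   with attributes `seed`, `summary`, `config_hash`, `tick_ms`.
#' @export
run_session <- function(molecules, trajectory, observables = "distance",
                        seed = 1, anchors = NULL, options = list()) {
  if (!length(observables)) stop("enable at least one observable")
  known <- c("distance", "electrostatics", "clash", "hbond", "proton",
             "saxs", "pcs", "contacts", "linker")
  bad <- setdiff(observables, known)
  if (length(bad)) stop("unknown observables: ", paste(bad, collapse = ", "))
  opts <- utils::modifyList(session_defaults(), options)
  set.seed(seed)
  ids <- names(molecules)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("molecules must be a named list")
  unknown <- setdiff(unique(trajectory$molecule), ids)
  if (length(unknown)) {
    fr <- trajectory$frame[match(unknown[1], trajectory$molecule)]
    stop(sprintf("frame %d references unknown molecule '%s'", fr, unknown[1]))
  }
  if (is.null(anchors)) anchors <- stats::setNames(rep(1L, length(ids)), ids)
  ds <- opts$distance_sites %||% default_charged_sites(molecules)

  proton_state <- NULL
  if ("proton" %in% observables)
    proton_state <- protonation_state(populations = opts$populations)
  linker_sim <- NULL

  frames <- sort(unique(trajectory$frame))
  current_pose <- lapply(ids, function(i) pose())
  names(current_pose) <- ids
  rows <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    fr <- frames[fi]
    sub <- trajectory[trajectory$frame == fr, , drop = FALSE]
    for (k in seq_len(nrow(sub)))
      current_pose[[sub$molecule[k]]] <- pose_from_row(sub[k, ])
    scene <- assemble_scene(lapply(ids, function(i)
      anchored_molecule(molecules[[i]], anchor_index = anchors[[i]],
                        pose = current_pose[[i]], id = i)))
    row <- list(frame = fr)
    obs_try <- function(expr) tryCatch(expr, error = function(e) {
      message(sprintf("frame %d: %s", fr, conditionMessage(e))); NA_real_
    })
    pa <- pb <- NULL
    if (!is.null(ds)) {
      pa <- obs_try(site_position(scene, ds$a$mol, ds$a$site))
      pb <- obs_try(site_position(scene, ds$b$mol, ds$b$site))
    }
    if ("distance" %in% observables)
      row$distance <- if (is.null(pa) || anyNA(pa) || anyNA(pb)) NA_real_
        else sqrt(sum((pa - pb)^2))
    if ("electrostatics" %in% observables) {
      ci <- obs_try({
        qa <- model_frame(molecules[[ds$a$mol]])$charge[ds$a$site]
        qb <- model_frame(molecules[[ds$b$mol]])$charge[ds$b$site]
        r <- sqrt(sum((pa - pb)^2))
        coulomb_interaction(qa, qb, r, opts$dielectric)
      })
      if (is.list(ci)) {
        row$energy <- ci$energy; row$force <- ci$force
        row$attractive <- ci$attractive
      } else {
        row$energy <- NA_real_; row$force <- NA_real_; row$attractive <- NA
      }
    }
    if ("clash" %in% observables)
      row$clash_count <- obs_try({
        if (length(ids) < 2) stop("clash observable needs two molecules")
        detect_clashes(scene_coords(scene, ids[1]),
                       scene_coords(scene, ids[2]),
                       threshold = opts$clash_threshold,
                       mode = opts$clash_mode)$count
      })
    hb <- NULL
    if (any(c("hbond", "proton") %in% observables) &&
        !is.null(opts$hbond_sites)) {
      hs <- opts$hbond_sites
      hb <- obs_try(detect_hbond(
        site_position(scene, hs$donor$mol, hs$donor$site),
        if (is.null(proton_state)) site_position(scene, hs$proton$mol,
                                                 hs$proton$site)
        else proton_state$proton_position,
        site_position(scene, hs$acceptor$mol, hs$acceptor$site)))
    }
    if ("hbond" %in% observables)
      row$hbond <- if (is.list(hb)) hb$display_bond else NA
    if ("proton" %in% observables) {
      eligible <- if (is.list(hb)) hb$transfer_eligible else TRUE
      proton_state <- proton_transfer_step(proton_state, eligible,
                                           opts$p_forward)
      row$holder <- proton_state$holder
    }
    if ("saxs" %in% observables)
      row$saxs_chi2 <- obs_try({
        calc <- saxs_debye(scene, opts$q_grid)
        if (is.null(opts$saxs_exp)) stop("saxs observable needs saxs_exp")
        fit_saxs(calc, opts$saxs_exp)$chi2
      })
    if ("pcs" %in% observables)
      row$pcs_ppm <- obs_try({
        if (is.null(opts$pcs_center)) stop("pcs observable needs pcs_center")
        probe <- site_position(scene, opts$pcs_probe$mol,
                               opts$pcs_probe$site)
        pcs_shift(probe, opts$pcs_center)
      })
    if ("contacts" %in% observables)
      row$contacts_satisfied <- obs_try({
        if (is.null(opts$contacts)) stop("contacts observable needs a table")
        rep <- score_contacts(opts$contacts, scene, d_sat = opts$d_sat)
        mean(rep$per_contact$satisfied)
      })
    if ("linker" %in% observables) {
      lrep <- obs_try({
        lk <- opts$linker
        if (is.null(lk)) stop("linker observable needs a linker spec")
        aa <- site_position(scene, lk$anchor_a$mol, lk$anchor_a$site)
        ab <- site_position(scene, lk$anchor_b$mol, lk$anchor_b$site)
        if (is.null(linker_sim)) {
          built <- build_linker_constraints(aa, ab,
                                            n_beads = lk$n_beads %||% 6,
                                            spacing = lk$spacing %||% 3.8)
          linker_sim <- list(
            state = dynamics_state(built$positions,
                                   temperature_target = lk$temperature %||% 1,
                                   fixed = built$fixed),
            constraints = built$constraints)
        }
        linker_sim$state$positions[1, ] <- aa
        linker_sim$state$positions[2, ] <- ab
        linker_sim$state <- dynamics_step(linker_sim$state,
                                          linker_sim$constraints)
        rep <- linker_report(linker_sim$state$positions,
                             linker_sim$constraints)
        list(linker_extension = rep$end_to_end,
             linker_entropy = rep$entropy, linker_strain = rep$strain)
      })
      if (is.list(lrep)) row <- c(row, lrep)
      else row <- c(row, list(linker_extension = NA_real_,
                              linker_entropy = NA_real_,
                              linker_strain = NA_real_))
    }
    rows[[fi]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  num <- vapply(out, is.numeric, logical(1))
  summary <- lapply(names(out)[num], function(cn) {
    v <- out[[cn]]
    c(mean = mean(v, na.rm = TRUE), min = suppressWarnings(min(v, na.rm = TRUE)),
      max = suppressWarnings(max(v, na.rm = TRUE)))
  })
  names(summary) <- names(out)[num]
  attr(out, "seed") <- seed
  attr(out, "summary") <- summary
  attr(out, "tick_ms") <- opts$tick_ms
  attr(out, "config_hash") <- config_hash(list(observables = observables,
                                               options = opts, seed = seed))
  class(out) <- c("session_result", "data.frame")
  out
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(x)), f)
  unname(tools::md5sum(f))
}

#' Write a session result as TSV
#'
#' `#`-prefixed header block (package version, seed, config hash, tick
#' metadata, per-column summary) followed by one row per frame.
#'
#' @param result a [run_session()] result.
#' @param path output path.
#' @export
write_session_tsv <- function(result, path) {
  stopifnot(inherits(result, "session_result"))
  hdr <- c(sprintf("# molscene %s session",
                   as.character(utils::packageVersion("molscene"))),
           sprintf("# seed: %d", attr(result, "seed")),
           sprintf("# config_hash: %s", attr(result, "config_hash")),
           sprintf("# tick_ms: %g", attr(result, "tick_ms")))
  sm <- attr(result, "summary")
  for (cn in names(sm))
    hdr <- c(hdr, sprintf("# summary %s: mean=%.6g min=%.6g max=%.6g",
                          cn, sm[[cn]]["mean"], sm[[cn]]["min"],
                          sm[[cn]]["max"]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(utils::write.table(result, con, sep = "\t",
                                      quote = FALSE, row.names = FALSE))
  invisible(path)
}

static_trajectory <- function(ids, n_frames, translations, scale = 1) {
  do.call(rbind, lapply(seq_len(n_frames), function(fr)
    do.call(rbind, lapply(seq_along(ids), function(k)
      data.frame(frame = fr, molecule = ids[k], qw = 1, qx = 0, qy = 0,
                 qz = 0, tx = translations[[k]][1], ty = translations[[k]][2],
                 tz = translations[[k]][3], scale = scale,
                 stringsAsFactors = FALSE)))))
}

#' Run a self-contained demo session
#'
#' Generates its fixture, runs the relevant computation, and writes inputs,
#' outputs and a plain-text report into `outdir`. Demos: `lys_glu`
#' (electrostatics + hydrogen bond + proton exchange), `linker` (six-bead
#' flexible linker dynamics and maximal extension), `saxs_fit` (pose
#' discrimination against a synthetic scattering target), `pcs_probe`
#' (shift map around a paramagnetic centre plus a spectrum trace).
#'
#' @param name demo name.
#' @param outdir output directory (created if needed).
#' @param seed RNG seed.
#' @return (invisibly) a list of the demo's headline numbers and file
#'   paths.
#' @export
run_demo <- function(name = c("lys_glu", "linker", "saxs_fit", "pcs_probe"),
                     outdir = ".", seed = 1) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown demo; available: lys_glu, linker, saxs_fit, pcs_probe"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rp <- function(...) file.path(outdir, ...)
  report <- c(sprintf("molscene %s demo '%s', seed %d",
                      as.character(utils::packageVersion("molscene")),
                      name, seed))
  out <- list()
  if (name == "lys_glu") {
    fx <- generate_fixture("lys_glu_pair", seed = seed)
    write_pdb(fx$lys, rp("lys_frag.pdb"))
    write_pdb(fx$glu, rp("glu_frag.pdb"))
    traj <- static_trajectory(c("lys", "glu"), 20,
                              list(c(0, 0, 0), c(9.5, 0, 0)))
    write_pose_trajectory(traj, rp("poses.txt"))
    res <- run_session(list(lys = fx$lys, glu = fx$glu), traj,
                       observables = c("distance", "electrostatics",
                                       "clash", "hbond", "proton"),
                       seed = seed,
                       options = list(
                         distance_sites = list(
                           a = list(mol = "lys", site = fx$titratable$lys_site),
                           b = list(mol = "glu", site = fx$titratable$glu_site)),
                         hbond_sites = list(
                           donor = list(mol = "lys",
                                        site = fx$titratable$lys_site),
                           proton = list(mol = "lys",
                                         site = fx$titratable$lys_proton),
                           acceptor = list(mol = "glu",
                                           site = fx$titratable$glu_site))))
    write_session_tsv(res, rp("session.tsv"))
    sim <- simulate_protonation(1e5, eligible = TRUE, seed = seed)
    out$fraction_lys <- sim$fraction_lys
    out$ratio <- sim$ratio
    report <- c(report,
                sprintf("stationary protonated-lysine fraction over 1e5 eligible ticks: %.4f (target 0.70)",
                        sim$fraction_lys),
                sprintf("LYS/GLU occupancy ratio: %.3f (target 2.33)",
                        sim$ratio),
                sprintf("session N-O distance: %.3f A; energy %.3f kcal/mol",
                        res$distance[1], res$energy[1]))
  } else if (name == "linker") {
    built <- build_linker_constraints(c(0, 0, 0), c(20, 0, 0))
    st <- dynamics_state(built$positions, temperature_target = 1,
                         fixed = built$fixed)
    run <- run_dynamics(st, built$constraints, n_steps = 2000, seed = seed,
                        record_every = 10)
    ext <- max_extension(built$constraints)
    rep0 <- linker_report(run$state$positions, built$constraints)
    out$max_extension <- ext$anchor_anchor
    out$final_strain <- rep0$strain
    out$max_violation <- run$max_violation
    utils::write.table(
      data.frame(tick = 10 * seq_along(run$kinetic_temperature),
                 kinetic_temperature = run$kinetic_temperature,
                 max_violation = run$violations),
      rp("linker_run.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    report <- c(report,
                sprintf("max relaxed anchor-anchor extension: %.2f A (7 x 3.8)",
                        ext$anchor_anchor),
                sprintf("constraint violation over run: max %.2e (tol 1e-3)",
                        run$max_violation),
                sprintf("final linker strain: %.3e; entropy %.3f k_B",
                        rep0$strain, rep0$entropy))
  } else if (name == "saxs_fit") {
    fx <- generate_fixture("synthetic_saxs_target", list(sigma = 0),
                           seed = seed)
    write_saxs_profile(fx$profile, rp("target_profile.dat"),
                       header = "synthetic noiseless Debye target")
    calc_true <- saxs_debye(fx$scene, fx$q_grid)
    fit_true <- fit_saxs(calc_true, fx$profile)
    disp_pose <- pose(rotation = fx$true_pose$q,
                      translation = fx$true_pose$translation + c(8, 0, 0))
    scene_disp <- assemble_scene(list(
      anchored_molecule(fx$domain_a, 1L, id = "A"),
      anchored_molecule(fx$domain_b, 1L, pose = disp_pose, id = "B")))
    fit_disp <- fit_saxs(saxs_debye(scene_disp, fx$q_grid), fx$profile)
    out$chi2_true <- fit_true$chi2
    out$chi2_displaced <- fit_disp$chi2
    report <- c(report,
                sprintf("chi2 at generating pose: %.3e (scale %.4f)",
                        fit_true$chi2, fit_true$scale),
                sprintf("chi2 at 8 A displaced pose: %.3f",
                        fit_disp$chi2))
  } else if (name == "pcs_probe") {
    ctr <- paramagnetic_center(delta_chi_ax = 2.0, delta_chi_rh = 0.5)
    set.seed(seed)
    grid <- expand.grid(x = seq(-15, 15, by = 5), y = seq(-15, 15, by = 5),
                        z = c(5, 10))
    shifts <- apply(grid, 1, function(p) pcs_shift(p, ctr))
    utils::write.table(cbind(grid, ppm = shifts), rp("pcs_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sp <- pcs_spectrum(shifts[1], linewidth = 0.05,
                       ppm_grid = seq(-3, 3, length.out = 1201))
    utils::write.table(sp, rp("spectrum.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$max_abs_shift <- max(abs(shifts))
    report <- c(report,
                sprintf("largest |shift| on the probe grid: %.3f ppm",
                        out$max_abs_shift))
  }
  writeLines(report, rp("report.txt"))
  out$report <- rp("report.txt")
  invisible(out)
}
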