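# Configuration files, trajectory store, and run summaries. Everything is
# plain text: YAML config, extended-XYZ frames, TSV sidecars, JSON summary.

#' Read a run configuration file
#'
#' The configuration is a flat YAML key-value file whose keys are exactly
#' the [gel_params()] argument names. Unknown keys are rejected; omitted
#' keys take the documented defaults, and each defaulted key is reported
#' via [message()].
#'
#' @param path Path to the YAML file.
#' @param quiet Suppress the defaulted-keys message.
#' @return A `gel_params` object.
#' @export
read_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("configuration error: file '%s' does not exist", path),
         call. = FALSE)
  }
  # YAML 1.1 would read the bare keys N/y/n as booleans; keep them literal
  keep <- function(x) x
  cfg <- tryCatch(
    yaml::yaml.load(paste(readLines(path), collapse = "\n"),
                    handlers = list("bool#yes" = keep, "bool#no" = keep)),
    error = function(e) {
      stop(sprintf("configuration error: cannot parse '%s': %s", path,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  if (is.null(cfg)) cfg <- list()
  params <- make_params(cfg)
  if (!quiet) {
    defaulted <- setdiff(setdiff(names(formals(gel_params)), names(cfg)),
                         c("sigma", "attach_range", "k_E")) # derived defaults
    if (length(defaulted) > 0) {
      message("defaulted parameters: ", paste(defaulted, collapse = ", "))
    }
  }
  params
}

#' Write a run configuration file
#'
#' @param params A `gel_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "gel_params"))
  keys <- names(formals(gel_params))
  yaml::write_yaml(params[keys], path)
  invisible(path)
}

fmt <- function(x) sprintf("%.17g", x)

#' Write a trajectory to a directory of plain-text files
#'
#' Layout: `frames.xyz` (extended XYZ; the atom name encodes filament and
#' monomer as `F<fil>M<mon>`, the comment line carries `frame=` and
#' `time=`), `motors.tsv` (`frame`, `time`, `fil_a`, `mon_a`, `fil_b`,
#' `mon_b`), `wall.tsv` (`frame`, `time`, `node`, `x`, `y`),
#' `observables.tsv`, and `params.yaml`. Coordinates are written at full
#' double precision so that a round trip is bit-identical.
#'
#' @param traj A `gel_trajectory` with stored frames.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(traj, dir) {
  stopifnot(inherits(traj, "gel_trajectory"))
  if (length(traj$frames) == 0) {
    stop("trajectory has no stored frames", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xyz <- file.path(dir, "frames.xyz")
  con <- file(xyz, "w")
  on.exit(close(con), add = TRUE)
  motor_rows <- list()
  wall_rows <- list()
  for (k in seq_along(traj$frames)) {
    st <- traj$frames[[k]]
    writeLines(as.character(nrow(st$positions)), con)
    writeLines(sprintf("frame=%d time=%s N=%d M=%d wall_l0=%s wall_kappa0=%s",
                       k, fmt(st$time), st$N, st$M, fmt(st$wall_l0),
                       fmt(st$wall_kappa0)), con)
    lab <- sprintf("F%dM%d", rep(seq_len(st$N), each = st$M),
                   rep(seq_len(st$M), times = st$N))
    writeLines(paste(lab, fmt(st$positions[, 1]), fmt(st$positions[, 2]),
                     fmt(st$positions[, 3])), con)
    if (nrow(st$motors) > 0) {
      motor_rows[[k]] <- data.frame(frame = k, time = st$time,
                                    fil_a = st$motors[, 1],
                                    mon_a = st$motors[, 2],
                                    fil_b = st$motors[, 3],
                                    mon_b = st$motors[, 4])
    }
    if (nrow(st$wall) > 0) {
      wall_rows[[k]] <- data.frame(frame = k, time = fmt(st$time),
                                   node = seq_len(nrow(st$wall)),
                                   x = fmt(st$wall[, 1]),
                                   y = fmt(st$wall[, 2]))
    }
  }
  mo <- if (length(motor_rows) > 0) {
    do.call(rbind, motor_rows)
  } else {
    data.frame(frame = integer(0), time = numeric(0), fil_a = integer(0),
               mon_a = integer(0), fil_b = integer(0), mon_b = integer(0))
  }
  write.table(mo, file.path(dir, "motors.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  wl <- if (length(wall_rows) > 0) {
    do.call(rbind, wall_rows)
  } else {
    data.frame(frame = integer(0), time = numeric(0), node = integer(0),
               x = numeric(0), y = numeric(0))
  }
  write.table(wl, file.path(dir, "wall.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(traj$observables, file.path(dir, "observables.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write_config(traj$params, file.path(dir, "params.yaml"))
  invisible(dir)
}

parse_xyz_comment <- function(line) {
  kv <- strsplit(strsplit(line, "\\s+")[[1]], "=")
  vals <- vapply(kv, function(p) p[2], character(1))
  names(vals) <- vapply(kv, function(p) p[1], character(1))
  vals
}

#' Read a trajectory from a directory
#'
#' Inverse of [write_trajectory()]. A truncated frames file raises a
#' corruption error naming the last intact frame.
#'
#' @param dir Directory written by [write_trajectory()].
#' @return A `gel_trajectory`.
#' @export
read_trajectory <- function(dir) {
  xyz <- file.path(dir, "frames.xyz")
  if (!file.exists(xyz)) stop("no frames.xyz in ", dir, call. = FALSE)
  lines <- readLines(xyz)
  params <- read_config(file.path(dir, "params.yaml"), quiet = TRUE)
  motors <- read.table(file.path(dir, "motors.tsv"), sep = "\t", header = TRUE)
  wall <- read.table(file.path(dir, "wall.tsv"), sep = "\t", header = TRUE)
  frames <- list()
  i <- 1
  k <- 0
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(lines[i]))
    if (is.na(nat) || i + 1 + nat > length(lines)) {
      stop(sprintf("corrupt trajectory: truncated after frame %d", k),
           call. = FALSE)
    }
    meta <- parse_xyz_comment(lines[i + 1])
    body <- lines[(i + 2):(i + 1 + nat)]
    parts <- strsplit(body, "\\s+")
    pos <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))), ncol = 3,
                  byrow = TRUE)
    if (any(!is.finite(pos))) {
      stop(sprintf("corrupt trajectory: unreadable coordinates in frame %d",
                   k + 1), call. = FALSE)
    }
    k <- k + 1
    N <- as.integer(meta[["N"]])
    M <- as.integer(meta[["M"]])
    mo <- motors[motors$frame == k, c("fil_a", "mon_a", "fil_b", "mon_b"),
                 drop = FALSE]
    wl <- wall[wall$frame == k, c("x", "y"), drop = FALSE]
    frames[[k]] <- gel_state(
      pos, N, M, motors = as.matrix(mo), wall = as.matrix(wl),
      wall_l0 = as.numeric(meta[["wall_l0"]]),
      wall_kappa0 = as.numeric(meta[["wall_kappa0"]]),
      time = as.numeric(meta[["time"]])
    )
    i <- i + 2 + nat
  }
  obs_path <- file.path(dir, "observables.tsv")
  obs <- if (file.exists(obs_path)) {
    tibble::as_tibble(read.table(obs_path, sep = "\t", header = TRUE))
  } else {
    tibble::tibble()
  }
  structure(list(params = params, seed = params$seed, frames = frames,
                 observables = obs),
            class = "gel_trajectory")
}

#' @rdname read_trajectory
#' @param frame Frame index (1-based).
#' @return For `read_frame`, a single `gel_state`.
#' @export
read_frame <- function(dir, frame) {
  tr <- read_trajectory(dir)
  if (frame < 1 || frame > length(tr$frames)) {
    stop("frame index out of range", call. = FALSE)
  }
  tr$frames[[frame]]
}

#' Summarise a run for the state diagram
#'
#' Collects everything needed to place one run on a state diagram: the
#' parameter echo, seed, final state label, vorticity, contraction-fit
#' parameters, time-averaged motor statistics and the final energy
#' breakdown.
#'
#' @param traj A `gel_trajectory`.
#' @param burn_in Fraction of initial frames excluded from time averages.
#' @return A list (class `run_summary`) serialisable with
#'   [write_run_summary()].
#' @export
run_summary <- function(traj, burn_in = 0.25) {
  stopifnot(inherits(traj, "gel_trajectory"))
  ob <- traj$observables
  keep <- ob$time >= burn_in * max(ob$time)
  fit <- if (nrow(ob) >= 8 && all(is.finite(ob$radius))) {
    glance(fit_contraction(ob[, c("time", "radius")],
                           t_max = traj$params$t_end))
  } else {
    NULL
  }
  vt <- tryCatch({
    tracks <- tidy(traj)
    v <- transverse_velocity(tracks,
                             v_scale = traj$params$b / traj$params$tau_b)
    t_cont <- if (!is.null(fit) && fit$contracted) fit$t_cont else Inf
    vorticity_stats(v, t_cont = t_cont)
  }, error = function(e) NULL)
  energy <- if (length(traj$frames) > 0) {
    eb <- energy_breakdown(traj$frames[[length(traj$frames)]], traj$params)
    setNames(as.list(eb$energy), eb$term)
  } else {
    NULL
  }
  structure(list(
    params = traj$params[names(formals(gel_params))],
    seed = traj$seed,
    final_state = ob$state[nrow(ob)],
    vorticity = if (!is.null(vt)) as.list(vt) else NULL,
    contraction = if (!is.null(fit)) as.list(fit) else NULL,
    n_mot_per_filament = mean(ob$n_mot[keep]) / traj$params$N,
    f_plus = mean(ob$f_plus[keep], na.rm = TRUE),
    final_energy = energy,
    version = as.character(utils::packageVersion("activegel"))
  ), class = "run_summary")
}

#' @rdname run_summary
#' @param summary A `run_summary`.
#' @param path Output JSON path.
#' @export
write_run_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
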