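#' File formats
#'
#' Plain-text exchange formats: extended XYZ for geometries and
#' trajectories (angstrom and fs at the file boundary, converted to
#' atomic units on load), a labeled-dataset format with one block per
#' fidelity, and a text checkpoint for surrogate models.  All floats are
#' written with 17 significant digits, so numeric round-trips are exact.
#'
#' @name io
NULL

fmt_num <- function(x) sprintf("%.17g", x)

format_fields <- function(fields) {
  paste(vapply(names(fields), function(k) {
    v <- fields[[k]]
    if (is.numeric(v)) v <- paste(fmt_num(v), collapse = ",")
    paste0(k, "=", v)
  }, ""), collapse = " ")
}

parse_fields <- function(line) {
  if (!nzchar(trimws(line))) return(list())
  parts <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) next
    val <- strsplit(kv[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(val))
    out[[kv[1]]] <- if (!anyNA(num)) num else kv[2]
  }
  out
}

#' Write frames as extended XYZ
#'
#' Each frame is a list with `coords` (`n x 3` matrix, angstrom),
#' optional `elements` (defaults to "X"), optional `velocities`
#' (`n x 3`, angstrom/fs, written as extra columns) and optional
#' `fields` (named key=value entries for the comment line; numeric
#' vectors are comma-joined).
#'
#' @param frames list of frames (a single frame is accepted too).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_extended_xyz <- function(frames, path) {
  if (!is.null(frames$coords)) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    xyz <- matrix(fr$coords, ncol = 3)
    n <- nrow(xyz)
    el <- fr$elements %||% rep("X", n)
    writeLines(as.character(n), con)
    writeLines(format_fields(fr$fields %||% list()), con)
    for (i in seq_len(n)) {
      ln <- paste(el[i], paste(fmt_num(xyz[i, ]), collapse = " "))
      if (!is.null(fr$velocities))
        ln <- paste(ln, paste(fmt_num(fr$velocities[i, ]), collapse = " "))
      writeLines(ln, con)
    }
  }
  invisible(path)
}

#' Read an extended XYZ file
#'
#' @param path input file path.
#' @return list of frames (`coords` n x 3 angstrom, `elements`,
#'   `velocities` when present, `fields` from the comment line).
#' @export
read_extended_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop(sprintf("malformed atom-count line %d: '%s'", i, lines[i]),
           call. = FALSE)
    if (i + 1L + n > length(lines))
      stop(sprintf("truncated frame starting at line %d", i), call. = FALSE)
    fields <- parse_fields(lines[i + 1L])
    coords <- matrix(NA_real_, n, 3)
    vels <- NULL
    el <- character(n)
    for (j in seq_len(n)) {
      toks <- strsplit(trimws(lines[i + 1L + j]), "[[:space:]]+")[[1]]
      if (length(toks) < 4)
        stop(sprintf("malformed coordinate line %d", i + 1L + j), call. = FALSE)
      el[j] <- toks[1]
      nums <- suppressWarnings(as.numeric(toks[-1]))
      if (anyNA(nums[1:3]))
        stop(sprintf("non-numeric coordinates at line %d", i + 1L + j),
             call. = FALSE)
      coords[j, ] <- nums[1:3]
      if (length(nums) >= 6) {
        if (is.null(vels)) vels <- matrix(NA_real_, n, 3)
        vels[j, ] <- nums[4:6]
      }
    }
    fr <- list(coords = coords, elements = el, fields = fields)
    if (!is.null(vels)) fr$velocities <- vels
    frames[[length(frames) + 1L]] <- fr
    i <- i + 2L + n
  }
  frames
}

## pad abstract model coordinates into n x 3 pseudo-atom layout
coords_to_xyz <- function(x) {
  n <- ceiling(length(x) / 3)
  m <- matrix(0, n, 3)
  m[seq_along(x)] <- x   # column-major fill is fine for a round-trip
  m
}

#' Export a trajectory as extended XYZ
#'
#' Comment-line fields per frame: `time_fs`, `active_state`,
#' `energies_hartree`; coordinates in angstrom (abstract model
#' coordinates are padded into pseudo-atom rows).
#'
#' @param trajectory a `trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(trajectory, path) {
  frames <- lapply(seq_along(trajectory$times_fs), function(i) {
    list(coords = coords_to_xyz(trajectory$coords[i, ]) * ANG_PER_BOHR,
         fields = list(time_fs = trajectory$times_fs[i],
                       active_state = trajectory$active[i],
                       energies_hartree = trajectory$energies[i, ],
                       n_coords = ncol(trajectory$coords),
                       termination = trajectory$termination))
  })
  write_extended_xyz(frames, path)
}

#' Read a trajectory exported by [write_trajectory_xyz()]
#'
#' @param path input path.
#' @return a minimal `trajectory` (times, coords in bohr, energies,
#'   active states, termination); velocities and hop records are not
#'   stored in the XYZ export.
#' @export
read_trajectory_xyz <- function(path) {
  frames <- read_extended_xyz(path)
  stop_if(length(frames) == 0, "no frames in file")
  nc <- as.integer(frames[[1]]$fields$n_coords %||% (3 * nrow(frames[[1]]$coords)))
  coords <- t(matrix(vapply(frames, function(fr)
    as.numeric(fr$coords)[seq_len(nc)] * BOHR_PER_ANG, numeric(nc)),
    nc, length(frames)))
  ns <- length(frames[[1]]$fields$energies_hartree)
  energies <- t(matrix(vapply(frames, function(fr)
    as.numeric(fr$fields$energies_hartree), numeric(ns)),
    ns, length(frames)))
  structure(list(
    times_fs = vapply(frames, function(fr) fr$fields$time_fs, 0),
    coords = coords, energies = energies,
    active = vapply(frames, function(fr) as.integer(fr$fields$active_state), 0L),
    hops = data.frame(), termination = frames[[1]]$fields$termination %||% "completed"),
    class = "trajectory")
}

## ---------------------------------------------------------------------------
## labeled datasets

#' Write a labeled dataset (one block per fidelity)
#'
#' Gradient-free fidelities store no gradient payload.  With
#' `append = TRUE` new fidelity blocks are added after the existing ones.
#'
#' @param dataset a `labeled_dataset`.
#' @param path output path.
#' @param append append to an existing file?
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, append = FALSE) {
  fids <- vapply(dataset, function(r) r$fidelity, "")
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  if (!append) writeLines("# gfnamd dataset v1", con)
  for (f in unique(fids)) {
    recs <- dataset[fids == f]
    S <- length(recs[[1]]$energies)
    C <- length(recs[[1]]$coords)
    same <- vapply(recs, function(r)
      length(r$energies) == S && length(r$coords) == C, TRUE)
    stop_if(!all(same),
            sprintf("fidelity '%s' mixes record dimensions", f))
    hg <- !is.null(recs[[1]]$gradients)
    stop_if(!all(vapply(recs, function(r) !is.null(r$gradients), TRUE) == hg),
            sprintf("fidelity '%s' mixes gradient availability", f))
    writeLines(sprintf("fidelity %s n_states %d n_coords %d has_gradients %d n_records %d",
                       f, S, C, as.integer(hg), length(recs)), con)
    for (r in recs) {
      nums <- c(r$coords, r$energies,
                if (hg) as.numeric(t(r$gradients)), r$weight %||% 1)
      writeLines(paste(fmt_num(nums), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read a labeled dataset
#'
#' @param path input path.
#' @return a `labeled_dataset`.
#' @export
read_dataset <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  records <- list()
  i <- 1L
  while (i <= length(lines)) {
    hd <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    stop_if(hd[1] != "fidelity" || length(hd) < 10,
            sprintf("malformed fidelity header: '%s'", lines[i]))
    f <- hd[2]
    S <- as.integer(hd[4]); C <- as.integer(hd[6])
    hg <- as.integer(hd[8]) == 1L; N <- as.integer(hd[10])
    for (j in seq_len(N)) {
      nums <- as.numeric(strsplit(trimws(lines[i + j]), "[[:space:]]+")[[1]])
      expected <- C + S + if (hg) S * C else 0
      stop_if(length(nums) != expected + 1,
              sprintf("record %d of fidelity '%s' has %d values, expected %d",
                      j, f, length(nums), expected + 1))
      rec <- list(coords = nums[1:C], fidelity = f,
                  energies = nums[(C + 1):(C + S)], gradients = NULL,
                  weight = nums[length(nums)])
      if (hg) rec$gradients <- matrix(nums[(C + S + 1):(C + S + S * C)],
                                      S, C, byrow = TRUE)
      records[[length(records) + 1L]] <- rec
    }
    i <- i + N + 1L
  }
  labeled_dataset(records)
}

## ---------------------------------------------------------------------------
## surrogate checkpoints

#' Write a surrogate model checkpoint (plain text)
#'
#' Stores the architecture, fidelity tags, input/output scalers, seeds
#' and all parameters at full precision.
#'
#' @param model a `surrogate_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# gfnamd surrogate checkpoint v1",
               paste("n_coords", model$n_coords),
               paste("n_states", model$n_states),
               paste("fidelities", paste(model$fidelities, collapse = ",")),
               paste("hidden", paste(model$hidden, collapse = ",")),
               paste("seed", model$seed),
               paste("trained", as.integer(model$trained)),
               paste("x_center", paste(fmt_num(model$x_center), collapse = ",")),
               paste("x_scale", paste(fmt_num(model$x_scale), collapse = ",")),
               paste("e_center", paste(fmt_num(model$e_center), collapse = ",")),
               paste("e_scale", fmt_num(model$e_scale)),
               paste("theta", paste(fmt_num(nn_pack(model$par)), collapse = ","))),
             con)
  invisible(path)
}

#' Read a surrogate model checkpoint
#'
#' @param path checkpoint path.
#' @return a `surrogate_model`.
#' @export
read_checkpoint <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  kv <- list()
  for (ln in lines) {
    sp <- regmatches(ln, regexpr(" ", ln), invert = TRUE)[[1]]
    kv[[sp[1]]] <- sp[2]
  }
  numv <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
  hidden <- if (nzchar(kv$hidden %||% "")) as.integer(numv(kv$hidden)) else integer(0)
  m <- build_surrogate(as.integer(kv$n_coords), as.integer(kv$n_states),
                       strsplit(kv$fidelities, ",", fixed = TRUE)[[1]],
                       hidden = hidden, seed = as.integer(kv$seed))
  m$x_center <- numv(kv$x_center); m$x_scale <- numv(kv$x_scale)
  m$e_center <- numv(kv$e_center); m$e_scale <- as.numeric(kv$e_scale)
  m$par <- nn_unpack(numv(kv$theta), m$shapes)
  m$trained <- as.integer(kv$trained) == 1L
  m
}

## ---------------------------------------------------------------------------
## run configuration

config_schema <- function() {
  c("model.type", "model.slope", "model.coupling", "model.mass",
    "model.a", "model.b", "model.c", "model.d",
    "model.k", "model.eps", "model.kappa", "model.lambda",
    "propagate.dt_fs", "propagate.t_max_fs", "propagate.reservoir_reduced",
    "propagate.uncertainty_threshold", "propagate.initial_state",
    "propagate.x0", "propagate.v0",
    "sample.n", "sample.seed",
    "dataset.n", "dataset.lower", "dataset.upper", "dataset.seed",
    "dataset.fidelity", "dataset.gradients",
    "meci.states", "meci.sigma0", "meci.alpha", "meci.gap_tol",
    "meci.grad_tol", "meci.x0",
    "seed")
}

#' Read a flat key-value run configuration
#'
#' Lines of the form `key = value`; `#` starts a comment; numeric values
#' (comma-separated for vectors) are parsed as numbers.  Unknown keys
#' are rejected.
#'
#' @param path config file path.
#' @return named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    stop_if(length(kv) != 2, sprintf("malformed config line: '%s'", ln))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    stop_if(!key %in% config_schema(),
            sprintf("unknown config key '%s'", key))
    num <- suppressWarnings(as.numeric(strsplit(val, ",", fixed = TRUE)[[1]]))
    cfg[[key]] <- if (!anyNA(num)) num else val
  }
  structure(cfg, class = "run_config")
}

#' Write a resolved run configuration
#'
#' @param cfg named list / `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    if (is.numeric(v)) v <- paste(fmt_num(v), collapse = ",")
    paste(k, "=", v)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

model_from_config <- function(cfg) {
  type <- cfg[["model.type"]] %||% "linear_crossing"
  switch(type,
    linear_crossing = model_linear_crossing(
      slope = cfg[["model.slope"]] %||% 0.01,
      coupling = cfg[["model.coupling"]] %||% 0.005,
      mass = cfg[["model.mass"]] %||% 2000),
    avoided_crossing = model_avoided_crossing(
      a = cfg[["model.a"]] %||% 0.01, b = cfg[["model.b"]] %||% 1.6,
      c = cfg[["model.c"]] %||% 0.005, d = cfg[["model.d"]] %||% 1.0,
      mass = cfg[["model.mass"]] %||% 2000),
    lvc3 = model_lvc3(
      k = cfg[["model.k"]] %||% 0.05,
      eps = cfg[["model.eps"]] %||% c(0, 0.08, 0.12),
      kappa = cfg[["model.kappa"]] %||% c(0, -0.06, -0.12),
      lambda = cfg[["model.lambda"]] %||% 0.02,
      mass = cfg[["model.mass"]] %||% 2000),
    stop(sprintf("unknown model.type '%s'", type), call. = FALSE))
}
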