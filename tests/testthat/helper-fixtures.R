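## shared fixtures for the test suite; everything is built in code

## short training schedule for unit tests (not the study conditions)
quick_schedule <- function(seed = 1, batch_size = 64, max_epochs = 250) {
  training_schedule(initial_lr = 0.003, plateau_patience = 20,
                    batch_size = batch_size, max_epochs = max_epochs,
                    seed = seed)
}

## minimal trajectory stub with a chosen final geometry / termination,
## sufficient for classification and yield statistics
stub_trajectory <- function(final_coords, termination = "completed",
                            hops = NULL, active = 1L, n_states = 2L) {
  coords <- matrix(final_coords, nrow = 1)
  structure(list(times_fs = 0,
                 coords = coords,
                 velocities = coords * 0,
                 energies = matrix(0, 1, n_states),
                 active = active,
                 uncertainty = 0,
                 hops = hops %||% data.frame(
                   time_fs = numeric(0), from_state = integer(0),
                   to_state = integer(0), probability = numeric(0),
                   accepted = logical(0), frustrated = logical(0),
                   frame = integer(0)),
                 termination = termination,
                 masses = rep(1, length(final_coords))),
            class = "trajectory")
}

## trajectory stub that hops from `from` to `to` at a given time and
## holds states on a frame grid (for population tests)
hopping_trajectory <- function(hop_time_fs, times_fs = seq(0, 60, by = 1),
                               from = 2L, to = 1L, n_states = 2L) {
  active <- ifelse(times_fs < hop_time_fs, from, to)
  n <- length(times_fs)
  structure(list(times_fs = times_fs,
                 coords = matrix(0, n, 1),
                 velocities = matrix(0, n, 1),
                 energies = matrix(0, n, n_states),
                 active = as.integer(active),
                 uncertainty = rep(0, n),
                 hops = data.frame(time_fs = hop_time_fs, from_state = from,
                                   to_state = to, probability = 1,
                                   accepted = TRUE, frustrated = FALSE,
                                   frame = which(times_fs >= hop_time_fs)[1]),
                 termination = "completed",
                 masses = 1),
            class = "trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
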