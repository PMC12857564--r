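#' Unit conversion constants
#'
#' All internal quantities are in Hartree atomic units (hartree, bohr,
#' atomic time, electron masses, hbar = 1).  Femtoseconds and angstroms
#' appear only at I/O boundaries and in analysis output.
#'
#' @format Named numeric constants.
#' @name units
NULL

#' @rdname units
#' @export
FS_PER_AU <- 1 / 41.341373335182114

#' @rdname units
#' @export
AU_PER_FS <- 41.341373335182114

#' @rdname units
#' @export
ANG_PER_BOHR <- 0.529177210903

#' @rdname units
#' @export
BOHR_PER_ANG <- 1 / 0.529177210903

#' Convert femtoseconds to atomic time units
#' @param t_fs time in fs
#' @return time in atomic units
#' @export
fs_to_au <- function(t_fs) t_fs * AU_PER_FS

#' Convert atomic time units to femtoseconds
#' @param t_au time in atomic units
#' @return time in fs
#' @export
au_to_fs <- function(t_au) t_au * FS_PER_AU

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
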