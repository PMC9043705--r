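#' Adapter for the published tablet-reaching deposit
#'
#' Maps an on-disk copy of the study's deposited data
#' (Dryad, \doi{10.6078/D1MX4P}) onto the canonical `trials.csv` /
#' `trajectories.csv` schema used by [process_dataset()]. The deposit is not
#' bundled and its layout is not fixed here: if `dir` already contains the
#' canonical CSV pair the adapter loads it directly; otherwise a `mapper`
#' function must be supplied that takes the directory and returns a list
#' with `trials` and `trajectories` in the canonical schemas (validated with
#' [validate_dataset()] before use).
#'
#' @param dir directory holding the downloaded deposit.
#' @param mapper optional function `dir -> list(trials, trajectories)`.
#' @return an `udl_dataset` (without latent truth table).
#' @export
read_dryad_deposit <- function(dir, mapper = NULL) {
  if (file.exists(file.path(dir, "trials.csv")) &&
      file.exists(file.path(dir, "params.json"))) {
    return(read_dataset(dir))
  }
  if (is.null(mapper)) {
    stop("No canonical dataset found in '", dir, "'. Download the deposit ",
         "(https://doi.org/10.6078/D1MX4P) and supply `mapper`, a function ",
         "mapping its layout to the canonical trials/trajectories schema ",
         "(see ?process_dataset).")
  }
  mapped <- mapper(dir)
  stopifnot(is.list(mapped), all(c("trials", "trajectories") %in%
                                   names(mapped)))
  ds <- structure(list(design = "external", params = NULL, seed = NA_integer_,
                       trials = tibble::as_tibble(mapped$trials),
                       latent = NULL,
                       trajectories = data.table::as.data.table(
                         mapped$trajectories)),
                  class = "udl_dataset")
  viol <- validate_dataset(ds)
  if (nrow(viol) > 0) {
    stop("mapped dataset fails validation: ", nrow(viol), " violation(s); ",
         "first: ", viol$message[1])
  }
  ds
}
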