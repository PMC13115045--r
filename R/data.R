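#' Packaged survival datasets
#'
#' Two classical complete survival datasets used throughout the package
#' examples and validation:
#' \describe{
#'   \item{\code{bladder}}{remission times (months) of 128 bladder cancer
#'     patients (Lee & Wang), a standard right-skewed heavy-tailed
#'     clinical benchmark.}
#'   \item{\code{guinea}}{survival times (days) of 72 guinea pigs
#'     (Bjerkedal), a classical biological-assay dataset.}
#' }
#'
#' @param name \code{"bladder"} or \code{"guinea"}.
#' @return List with \code{name}, numeric vector \code{values}, \code{n}
#'   and a \code{source} citation string.
#' @examples
#' d <- ll_data("bladder")
#' range(d$values)
#' @export
ll_data <- function(name = c("bladder", "guinea")) {
  name <- tryCatch(match.arg(name), error = function(e) {
    stop("unknown dataset; available fixtures: \"bladder\", \"guinea\"",
         call. = FALSE)
  })
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "llpredict", mustWork = TRUE)
  values <- utils::read.csv(path)$time
  src <- switch(name,
    bladder = "Lee & Wang, Statistical Methods for Survival Data Analysis",
    guinea = "Bjerkedal, Am. J. Hygiene 72 (1960)")
  list(name = name, values = values, n = length(values), source = src)
}
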