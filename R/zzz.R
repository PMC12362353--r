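#' @import data.table
#' @importFrom stats quantile rnorm runif rbinom rpois rbeta setNames plogis
#' @importFrom stats pt qt complete.cases
#' @keywords internal
"_PACKAGE"

# data.table non-standard evaluation columns
utils::globalVariables(c(
  ".", ".N", ".SD", "year", "month", "season", "ym", "wt", "cell", "cutoff",
  "percentile", "pidx", "cluster_id", "birth_id", "bym", "wym", "n_days",
  "complete", "n_ok", "precip", "mean_precip", "birth_year", "birth_month",
  "mother_age", "mother_age_sq", "electricity", "residence_duration",
  "interview_ym", "p_true", "neonatal_death", "prenatal_visits", "lon", "lat",
  "country", "residence_type", "pcell", "cell1", "cell2", "missing", "date",
  ".stratum", ".g2", ".x_g2", "term", "n_singletons"))

.onLoad <- function(libname, pkgname) {
  # data.table is imported for its [.data.table semantics
  invisible()
}
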