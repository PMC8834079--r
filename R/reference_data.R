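#' Published group summaries for the green vs yellow-leaf comparison
#'
#' Per-group summary statistics (n, mean, SE) of the pigment contents,
#' MR/MRo slope parameters and JIP-test parameters published for wild-type
#' (green, `WT`) versus yellow-leaf mutant (`MT`) *Torreya grandis*
#' 'Merrillii' leaves. These are the values against which the package's
#' internal-consistency identities and summary-statistics comparisons are
#' exercised; the underlying raw kinetics were never deposited, which is
#' why the synthetic generator exists.
#'
#' @param table Optional filter: `"pigments"`, `"mr"` or `"jip"`.
#' @return Data frame with columns `table`, `parameter`, `group`, `n`,
#'   `mean`, `se`.
#' @export
reference_summaries <- function(table = NULL) {
  path <- system.file("extdata", "reference_summaries.csv",
                      package = "ojipsuite", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(table)) df <- df[df$table == table, ]
  df
}
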