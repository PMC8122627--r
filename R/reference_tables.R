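# Published oligosaccharide benchmark tables shipped as a plain-text
# fixture: experimental and calculated T1/T2/NOE for six systems (R2R, BGL,
# GGM, TRI, LNF, GCY) at their optimal Reff, used for deviation-arithmetic
# validation. The printed per-cell e() columns were derived from unrounded
# calculated values and can differ by +-0.1 from deviations recomputed from
# the printed numbers.

#' Benchmark oligosaccharide relaxation table
#'
#' @return data.frame of 32 rows with experimental (`exp_*`) and calculated
#'   (`calc_*`) T1 (ms), T2 (ms) and NOE, conditions (T, viscosity,
#'   spectrometer frequency), the optimal `reff_A` and the printed
#'   percentage-deviation columns (`e_*`).
#' @export
reference_deviation_table <- function() {
  path <- system.file("extdata", "oligosaccharide_tables.csv",
                      package = "sfbnmr")
  if (path == "") path <- file.path("inst", "extdata",
                                    "oligosaccharide_tables.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Long-form (observable, exp, calc) view of the benchmark table
#'
#' @return data.frame ready for [deviation_summary()].
#' @export
reference_deviation_pairs <- function() {
  tab <- reference_deviation_table()
  do.call(rbind, lapply(c("T1", "T2", "NOE"), function(o) {
    suff <- if (o == "NOE") "NOE" else paste0(o, "_ms")
    data.frame(observable = o, system = tab$system, freq_MHz = tab$freq_MHz,
               exp = tab[[paste0("exp_", suff)]],
               calc = tab[[paste0("calc_", suff)]])
  }))
}
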