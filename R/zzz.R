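#' @keywords internal
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @useDynLib electrometry, .registration = TRUE
"_PACKAGE"

# column names used inside aes() and dplyr verbs
utils::globalVariables(c("b", "q_calc_abs", "fitted", "in_fit_window",
                         "psi", "dt_ms", "logpsi", "R_g", "R", "gamma",
                         "eta", "x", "y", "z"))
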