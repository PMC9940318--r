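#' @useDynLib graftflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx chisq.test fisher.test binom.test t.test wilcox.test
#' @importFrom utils read.csv write.csv head tail
NULL

## Internal unit system is CGS (cm, s, g, dyn/cm^2, ml/s).
## All user-facing interfaces use mmHg and ml/min.

#' Unit conversion constants
#'
#' Conversion factors between the interface units (mmHg, ml/min) and the
#' CGS units (dyn/cm^2, ml/s) used internally by the solver.
#'
#' @format `MMHG_PER_DYN_CM2` is the reciprocal of `DYN_CM2_PER_MMHG`
#'   (1 mmHg = 1333.22 dyn/cm^2).
#' @name units
NULL

#' @rdname units
#' @export
DYN_CM2_PER_MMHG <- 1333.22

#' @rdname units
#' @export
MMHG_PER_DYN_CM2 <- 1 / 1333.22

mmHg_to_cgs <- function(p) p * DYN_CM2_PER_MMHG
cgs_to_mmHg <- function(p) p * MMHG_PER_DYN_CM2

## resistance mmHg.s/ml -> dyn.s/cm^5 and back
res_to_cgs <- function(r) r * DYN_CM2_PER_MMHG
res_to_mmHg <- function(r) r * MMHG_PER_DYN_CM2

## compliance ml/mmHg -> cm^5/dyn
cap_to_cgs <- function(c) c / DYN_CM2_PER_MMHG
cap_to_mmHg <- function(c) c * DYN_CM2_PER_MMHG
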