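# Reference confusion matrices from the clinical validation of this grading
# approach: 118 expert-consensus-graded colonic biopsies, split 79 training /
# 39 testing. Shipped as plain CSV under inst/extdata; rows are the experts'
# consensus grade, columns the system classification.

#' Reference confusion matrices of the clinical validation study
#'
#' Confusion matrices (reference grade in rows, system classification in
#' columns) from the clinical validation of this grading approach on 118
#' expert-consensus-graded biopsies: the training phase (79 cases) and the
#' testing phase (39 cases). \code{"overall"} returns their elementwise sum.
#'
#' @param phase \code{"training"}, \code{"testing"} or \code{"overall"}.
#' @return 4x4 integer matrix with grade dimnames.
#' @examples
#' referenceConfusion("testing")
#' @export
referenceConfusion <- function(phase = c("training", "testing", "overall")) {
  phase <- match.arg(phase)
  readOne <- function(p) {
    f <- system.file("extdata", paste0("confusion_", p, ".csv"),
                     package = "cryptArch", mustWork = TRUE)
    m <- as.matrix(utils::read.csv(f, row.names = 1L))
    dimnames(m) <- list(reference = gradeLevels(), system = gradeLevels())
    m
  }
  if (phase == "overall") readOne("training") + readOne("testing")
  else readOne(phase)
}
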