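# shared small synthetic study, built once per test run
.studyCache <- new.env()

smallConfig <- function() {
  simConfig(nPairs = 200, nSingletonA = 80, nSingletonD = 80,
            nScaffoldA = 10, nScaffoldD = 10, seed = 77)
}

smallStudy <- function() {
  if (is.null(.studyCache$std))
    .studyCache$std <- simulateHomoeoStudy(smallConfig())
  .studyCache$std
}

studyCounts <- function(std = smallStudy())
  SummarizedExperiment::assay(std$experiment, "counts")
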