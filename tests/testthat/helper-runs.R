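# memoised reference runs shared across test files (each ~0.2 s but reused a lot)
.runCache <- new.env(parent = emptyenv())

refCoupled <- function(example) {
  key <- paste0("coupled_", example)
  if (is.null(.runCache[[key]])) .runCache[[key]] <- runCoupled(example)
  .runCache[[key]]
}

refDroop <- function() {
  if (is.null(.runCache$droop)) .runCache$droop <- simulateDroop()
  .runCache$droop
}

refBounds <- function(example) {
  cast <- switch(example,
                 uptake = castUptakeSubsystem,
                 growth = castGrowthSubsystem)
  estimateDisturbanceBounds(cast(refDroop()))
}
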