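# Shared fixtures, built once per session and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# A small cohort for fast pipeline tests.
smallCohort <- function() {
  memo("small", function()
    generateCohort(GeneratorConfig(nThrombi = 10L, totalSlices = 20L,
                                   seed = 11L)))
}

# The emulated ex vivo cohort layout (48 thrombi, 188 slices).
exvivoCohort <- function() {
  memo("exvivo", function() generateCohort(GeneratorConfig("exvivo", seed = 1L)))
}

# A hand-built slice with known content: constant channel values inside a
# rectangular mask on an (h x w) canvas.
flatSlice <- function(values = c(10, 0.1, 50), h = 12L, w = 14L,
                      maskRows = 4:9, maskCols = 5:10, id = "T0001",
                      index = 1L) {
  mask <- matrix(0, h, w)
  mask[maskRows, maskCols] <- 1
  ch <- array(0, c(h, w, 3L),
              dimnames = list(NULL, NULL, c("r2star", "qsm", "gre")))
  for (k in 1:3) ch[, , k] <- values[k] * mask
  new("SliceImage", thrombusId = id, sliceIndex = index, channels = ch,
      mask = mask)
}

# A slice with reproducible non-constant content inside the mask.
texturedSlice <- function(seed = 1L, h = 49L, w = 56L, id = "T0001",
                          index = 1L) {
  set.seed(seed)
  mask <- matrix(0, h, w)
  mask[10:40, 12:45] <- 1
  ch <- array(0, c(h, w, 3L),
              dimnames = list(NULL, NULL, c("r2star", "qsm", "gre")))
  for (k in 1:3) ch[, , k] <- matrix(rnorm(h * w, k * 10, 3), h, w) * mask
  new("SliceImage", thrombusId = id, sliceIndex = index, channels = ch,
      mask = mask)
}
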