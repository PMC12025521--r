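# Shared fixtures built in code. Small phantoms keep unit tests fast; the
# acceptance suite uses the full-size defaults.

# a compact 3-interface phantom spec (valid for either region="leg" layout
# checks or generic band-recovery tests)
miniSpec <- function(speckleSigma = 0, seed = 1L) {
  phantomSpec("abdomen", "longitudinal", rows = 160L, cols = 120L,
              marginPx = 10L, speckleSigma = speckleSigma, seed = seed,
              boundaries = data.frame(
                structure_id = c("skin", "fascia_superficial",
                                 "muscle_wall", "peritoneum",
                                 "peritoneal_deep"),
                row = c(30, 60, 90, 110, 135),
                brightness = c(210, 190, 200, 195, 185),
                thickness = 4,
                stringsAsFactors = FALSE),
              zoneMeans = c(70, 50, 55, 75, 45, 35))
}

# a bright-rectangle ROI fixture spanning the image centre, with optional
# sub-threshold clutter outside
roiFixture <- function(h = 100L, w = 100L, top = 21L, bottom = 60L,
                       left = 31L, right = 70L, value = 200,
                       clutterMax = 0) {
  px <- if (clutterMax > 0)
    matrix(runif(h * w, 0, clutterMax), h, w)
  else matrix(0, h, w)
  px[top:bottom, left:right] <- value
  px
}

# a minimal StructureDetection for geometry-level tests
fakeDetection <- function(id, row, top = row - 5L, bottom = row + 5L,
                          left = 0L, right = 30L, score = 0.9,
                          flag = "") {
  StructureDetection(
    match = MatchResult(structureId = id, score = score,
                        bbox = ROIBox(left, right, top, bottom)),
    interfaceRow = row, flag = flag)
}
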