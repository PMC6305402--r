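test_that("compartments partition retained objects and areas add up", {
  s <- tinySlide()
  o <- cellData(s)
  expect_true(all(o$compartment %in% c("tumor", "non_tumor")))
  a <- regionAreas(s)
  expect_equal(a[["tumor"]] + a[["non_tumor"]], a[["entire"]],
               tolerance = 1e-12)
  expect_equal(a[["entire"]], 1)     # mm^2
  expect_equal(a[["tumor"]], 0.25)
  # quadrant assignment, boundary points belong to the tumor (precedence)
  expect_equal(as.character(compartmentOf(c(100, 900, 500, -5),
                                          c(100, 900, 500, -5),
                                          slideRegions(s))),
               c("tumor", "non_tumor", "tumor", "outside"))
})

test_that("objects outside tissue and inside exclusions are dropped", {
  s <- makeSlide(
    data.frame(x = c(100, -5, 500), y = c(100, -5, 500),
               marker = "Ki67", proliferating = TRUE),
    tissue = rectRing(0, 0, 1000, 1000),
    exclusions = rectRing(400, 400, 600, 600))
  expect_equal(nrow(cellData(s)), 1L)
  expect_equal(s@log$n_outside, 1L)
  expect_equal(s@log$n_excluded, 1L)
  # exclusion area is subtracted before anything else
  expect_equal(regionAreas(s)[["entire"]], 1 - 0.04)
})

test_that("tumor absent leaves an empty tumor compartment, not an error", {
  s <- makeSlide(data.frame(x = 500, y = 500, marker = "CD4",
                            proliferating = FALSE),
                 tissue = rectRing(0, 0, 1000, 1000))
  expect_equal(regionAreas(s)[["tumor"]], 0)
  expect_equal(regionAreas(s)[["non_tumor"]], 1)
  expect_equal(as.character(cellData(s)$compartment), "non_tumor")
})

test_that("slide files round-trip through GeoJSON + CSV exactly", {
  dir <- withr::local_tempdir()
  coh <- list(slides = list(tiny = tinySlide()),
              labels = data.frame(slide_id = "tiny", label = "A"))
  writeCohort(coh, dir)
  back <- readCohort(dir)
  s2 <- back$slides$tiny
  expect_equal(nrow(cellData(s2)), nrow(cellData(tinySlide())))
  expect_equal(regionAreas(s2), regionAreas(tinySlide()), tolerance = 1e-9)
  expect_equal(cellData(s2)$marker, cellData(tinySlide())$marker)
  expect_equal(as.character(cellData(s2)$compartment),
               as.character(cellData(tinySlide())$compartment))
})

test_that("loader rejects malformed inputs with informative errors", {
  dir <- withr::local_tempdir()
  # no tissue polygon
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature", properties = list(role = "tumor"),
    geometry = list(type = "Polygon",
                    coordinates = list(list(c(0, 0), c(1, 0), c(1, 1),
                                            c(0, 0)))))))
  bad <- file.path(dir, "bad.geojson")
  jsonlite::write_json(gj, bad, auto_unbox = TRUE, digits = NA)
  obj <- file.path(dir, "obj.csv")
  writeLines(c("slide_id,x_um,y_um,marker,proliferating",
               "s,100,100,Ki67,1"), obj)
  expect_error(loadSlide(bad, obj), "tissue")
  # malformed marker row reports the row number
  writeCohort(list(slides = list(s = tinySlide()),
                   labels = data.frame(slide_id = "s", label = "A")), dir)
  writeLines(c("slide_id,x_um,y_um,marker,proliferating",
               "s,100,100,Ki67,1", "s,200,200,CD19,0"),
             file.path(dir, "s_objects.csv"))
  expect_error(loadSlide(file.path(dir, "s_regions.geojson"),
                         file.path(dir, "s_objects.csv")), "2")
  # Ki67 must be proliferating
  writeLines(c("slide_id,x_um,y_um,marker,proliferating",
               "s,100,100,Ki67,0"), file.path(dir, "s_objects.csv"))
  expect_error(loadSlide(file.path(dir, "s_regions.geojson"),
                         file.path(dir, "s_objects.csv")), "Ki67")
})

test_that("object-set catalog has 10 entries with deterministic membership", {
  cat10 <- objectSetCatalog()
  expect_length(cat10, 10L)
  o <- cellData(tinySlide())
  m <- icFeatures:::membershipMatrix(o, names(cat10), cat10)
  # union structure: any = prolif | nonprolif, Tcell = CD4 | CD8
  expect_equal(m[, "CD4_any"], m[, "CD4_prolif"] | m[, "CD4_nonprolif"])
  expect_equal(m[, "Tcell_any"], m[, "CD4_any"] | m[, "CD8_any"])
  expect_equal(m[, "Tcell_prolif"], m[, "CD4_prolif"] | m[, "CD8_prolif"])
  expect_false(any(m[, "Ki67"] & m[, "Tcell_any"]))
})
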