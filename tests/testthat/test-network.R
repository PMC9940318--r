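test_that("a minimal single-vessel network assembles and validates", {
  net <- single_vessel_net()
  expect_s3_class(net, "coronary_network")
  expect_equal(nrow(net$segments), 1L)
  expect_equal(nrow(net$junctions), 0L)
  expect_length(validate_network(net), 0L)
})

test_that("validate_network reports structural violations without throwing", {
  net <- single_vessel_net()
  ## leaf with no terminal
  broken <- unclass(net)
  broken$terminals <- broken$terminals[0, ]
  v <- validate_network(broken)
  expect_true(any(grepl("distal end unattached", v)))
  ## stenosis outside its host
  broken2 <- unclass(net)
  broken2$stenoses <- stenosis_element("s", "V", 15, 80, 1)
  expect_true(any(grepl("position outside host", validate_network(broken2))))
  ## dangling junction reference
  broken3 <- unclass(net)
  broken3$junctions <- data.frame(junction = "J", segment = c("V", "ghost"),
                                  end = c("distal", "proximal"))
  expect_true(any(grepl("unknown segment", validate_network(broken3))))
  ## invariant violations in element parameters
  broken4 <- unclass(net)
  broken4$terminals$C <- -1
  expect_true(any(grepl("R1, R2, C", validate_network(broken4))))
})

test_that("network JSON round-trip is lossless field-wise", {
  net <- patient_archetype(3)
  f <- tempfile(fileext = ".json")
  save_network(net, f)
  net2 <- load_network(f)
  for (nm in setdiff(names(net), "globals"))
    expect_equal(net2[[nm]], net[[nm]], tolerance = 1e-12, info = nm)
  expect_equal(net2$globals$aortic$samples, net$globals$aortic$samples,
               tolerance = 1e-12)
  expect_equal(net2$globals$period, net$globals$period)
  ## grafted networks round-trip too
  g <- apply_configuration(net, "H")
  f2 <- tempfile(fileext = ".json")
  save_network(g, f2)
  g2 <- load_network(f2)
  for (nm in setdiff(names(g), "globals"))
    expect_equal(g2[[nm]], g[[nm]], tolerance = 1e-12, info = nm)
})

test_that("load_network rejects missing files and foreign documents", {
  expect_error(load_network(tempfile()), "no such file")
  f <- tempfile(fileext = ".json")
  writeLines('{"foo": 1}', f)
  expect_error(load_network(f), "format")
})

test_that("empty networks are rejected at save time", {
  net <- single_vessel_net()
  net$segments <- net$segments[0, ]
  expect_error(save_network(net, tempfile()), "invalid")
})

test_that("CSV import builds the same topology as the constructors", {
  net <- symmetric_bifurcation_net()
  d <- tempfile()
  dir.create(d)
  write.csv(net$segments, file.path(d, "seg.csv"), row.names = FALSE)
  write.csv(net$junctions, file.path(d, "rel.csv"), row.names = FALSE)
  write.csv(net$terminals, file.path(d, "ter.csv"), row.names = FALSE)
  write.csv(net$inflows, file.path(d, "inf.csv"), row.names = FALSE)
  net2 <- import_network_csv(file.path(d, "seg.csv"), file.path(d, "rel.csv"),
                             terminals_csv = file.path(d, "ter.csv"),
                             inflows_csv = file.path(d, "inf.csv"))
  expect_equal(net2$segments$id, net$segments$id)
  expect_length(validate_network(net2), 0L)
})

test_that("segment splitting preserves geometry and remaps references", {
  net <- single_vessel_net(radius = 0.3, taper_to = 0.2, length = 10)
  net$markers <- data.frame(site = "LAD", segment = "V", position_cm = 7)
  net$stenoses <- stenosis_element("s1", "V", 3, 80, 1)
  sp <- graftflow:::split_segment_at(net, "V", 5)
  net2 <- sp$net
  expect_length(validate_network(net2), 0L)
  i <- match(sp$prox_id, net2$segments$id)
  j <- match(sp$dist_id, net2$segments$id)
  expect_equal(net2$segments$length_cm[i] + net2$segments$length_cm[j], 10)
  expect_equal(net2$segments$radius_dist_cm[i],
               net2$segments$radius_prox_cm[j])
  expect_equal(net2$segments$radius_dist_cm[i], 0.25)  # linear taper at 5 cm
  ## marker beyond the cut moves to the distal piece with shifted position
  expect_equal(net2$markers$segment, sp$dist_id)
  expect_equal(net2$markers$position_cm, 2)
  ## stenosis before the cut stays on the proximal piece
  expect_equal(net2$stenoses$host_segment, sp$prox_id)
  expect_equal(net2$stenoses$position_cm, 3)
})

test_that("side-branch population follows the spacing rule deterministically", {
  net <- single_vessel_net(length = 6)
  net$segments$territory <- "LAD"
  net$terminals$territory <- "LAD"
  ## spacing 2 cm on a 6 cm vessel: branches at 2 and 4 only
  out <- populate_side_branches(net, spacing_cm = 2)
  expect_equal(sum(grepl("\\.b", out$segments$id)), 2L)
  expect_equal(nrow(out$terminals), 3L)  # original + 2 branch terminals
  ## zero-branch rule (spacing beyond the vessel) is the identity
  out0 <- populate_side_branches(net, spacing_cm = 10)
  expect_equal(out0$segments$id, net$segments$id)
  ## identical calls give identical networks
  expect_equal(populate_side_branches(net, spacing_cm = 2), out)
  expect_error(populate_side_branches(net, radius_ratio = 1.2), "radius_ratio")
})
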