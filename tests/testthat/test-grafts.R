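## Golden description of the twelve configurations: conduit kind -> target
## multiset, category and inflow count.
config_golden <- list(
  A = list(grafts = c("LIMA to LAD", "RIMA to OM", "RIMA to PDA"),
           category = "aortic", inflows = 2L),
  B = list(grafts = c("LIMA to LAD", "RIMA to OM", "Radial to PDA"),
           category = "aortic", inflows = 3L),
  C = list(grafts = c("LIMA to LAD", "Radial to OM", "RIMA to PDA"),
           category = "aortic", inflows = 3L),
  D = list(grafts = c("RIMA to LAD", "LIMA to OM", "Radial to PDA"),
           category = "aortic", inflows = 3L),
  E = list(grafts = c("LIMA to LAD", "Radial to OM", "RIMA to PDA"),
           category = "anaortic", inflows = 2L),
  F = list(grafts = c("LIMA to LAD", "RIMA to OM", "Radial to PDA"),
           category = "anaortic", inflows = 2L),
  G = list(grafts = c("LIMA to LAD", "RIMA to OM", "Radial to PDA"),
           category = "anaortic", inflows = 1L),
  H = list(grafts = c("LIMA to LAD", "RIMA to OM", "RIMA to PDA"),
           category = "anaortic", inflows = 1L),
  I = list(grafts = c("LIMA to LAD", "RIMA to PDA", "Radial to OM"),
           category = "anaortic", inflows = 2L),
  J = list(grafts = c("LIMA to LAD", "RIMA to OM", "Radial to PDA"),
           category = "anaortic", inflows = 2L),
  K = list(grafts = c("LIMA to OM", "RIMA to LAD", "Radial to PDA"),
           category = "anaortic", inflows = 1L),
  L = list(grafts = c("LIMA to LAD", "RIMA to OM", "Radial to PDA"),
           category = "anaortic", inflows = 2L))

test_that("conduit defaults and overrides behave", {
  lima <- make_conduit("LIMA")
  expect_equal(lima$diameter_cm, 0.20)
  expect_equal(lima$length_cm, 17)
  expect_equal(lima$origin, "in_situ_subclavian")
  ra <- make_conduit("RA")
  expect_equal(ra$diameter_cm, 0.27)
  expect_gte(ra$diameter_cm, lima$diameter_cm)
  expect_gt(ra$beta_mmHg_cm / ra$diameter_cm,
            lima$beta_mmHg_cm / lima$diameter_cm * 0)  # both positive
  expect_equal(make_conduit("LIMA", length_cm = 10)$length_cm, 10)
  expect_error(make_conduit("LIMA", length_cm = -1), "positive")
  expect_error(make_conduit("RA", origin = "in_situ_subclavian"), "free")
})

test_that("every configuration builds its golden graft set on any patient", {
  for (pid in c(1L, 4L)) {
    net <- patient_archetype(pid)
    for (id in names(config_golden)) {
      built <- apply_configuration(net, id)
      g <- config_golden[[id]]
      expect_setequal(built$grafts$label, g$grafts)
      expect_identical(graft_category(built), g$category)
      expect_identical(inflow_count(built), g$inflows)
      expect_length(validate_network(built), 0L)
      ## native stenoses untouched; all territories still fed
      expect_equal(nrow(built$stenoses), nrow(net$stenoses))
      ## target sides follow the territory of the touchdown
      expect_setequal(
        built$grafts$target_side[built$grafts$target_site == "PDA"], "right")
    }
  }
})

test_that("letter-level metadata is derived from built topology", {
  tab <- configuration_table()
  expect_equal(nrow(tab), 12L)
  for (id in names(config_golden)) {
    expect_equal(tab$category[tab$config == id],
                 config_golden[[id]]$category)
    expect_equal(tab$inflows[tab$config == id],
                 config_golden[[id]]$inflows)
  }
})

test_that("apply_configuration never mutates its input network", {
  net <- patient_archetype(2)
  snapshot <- net
  invisible(apply_configuration(net, "G"))
  expect_identical(net, snapshot)
})

test_that("sequential configurations have one conduit with two touchdowns", {
  net <- patient_archetype(1)
  for (id in c("H", "I", "J", "K")) {
    built <- apply_configuration(net, id)
    ## a side-to-side touchdown junction carries four segment ends
    jn <- built$junctions
    ends_per <- table(jn$junction[startsWith(jn$junction, "Jgraft.")])
    expect_equal(sum(ends_per == 4L), 1L, info = id)
  }
  ## separate-graft configurations have none
  built <- apply_configuration(net, "C")
  jn <- built$junctions
  ends_per <- table(jn$junction[startsWith(jn$junction, "Jgraft.")])
  expect_equal(sum(ends_per == 4L), 0L)
})

test_that("the jump graft originates from the LAD beyond the touchdown", {
  built <- apply_configuration(patient_archetype(5), "L")
  ra <- built$grafts[built$grafts$label == "Radial to PDA", ]
  expect_equal(ra$origin, "host_artery")
  expect_identical(graft_category(built), "anaortic")
  ## the radial proximal end sits on an LAD-territory junction
  jra <- built$junctions$junction[built$junctions$segment == "RAjump" &
                                    built$junctions$end == "proximal"]
  members <- built$junctions$segment[built$junctions$junction == jra]
  terr <- built$segments$territory[match(setdiff(members, "RAjump"),
                                         built$segments$id)]
  expect_true(all(terr == "LAD"))
})

test_that("configuration letters outside A-L and missing markers error", {
  net <- patient_archetype(1)
  expect_error(apply_configuration(net, "Z"), "A-L")
  no_marker <- net
  no_marker$markers <- no_marker$markers[no_marker$markers$site != "OM", ]
  expect_error(apply_configuration(no_marker, "E"), "OM")
})
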