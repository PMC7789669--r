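test_that("reaction tables load, validate and round-trip exactly", {
  path <- write_toy_model_file()
  model <- load_model(path)
  expect_equal(nrow(model$reactions), 29)
  expect_equal(model$objective, "BIOMASS")
  expect_identical(model$reactions$stoichiometry,
                   toy_model()$reactions$stoichiometry)
  expect_identical(model$reactions$insertable, toy_model()$reactions$insertable)

  # second round trip is exact
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_reaction_table(model, path2)
  expect_identical(readLines(path), readLines(path2))

  # undeclared metabolite errors with the reaction id
  expect_error(
    metabolic_model(
      tibble::tibble(id = "R1", stoichiometry = list(c(X = -1)),
                     lb = 0, ub = 10, genes = "", insertable = FALSE),
      metabolites = "A", objective = "R1"),
    "X", class = "anaerodesign_model_error")
  # inverted bounds
  expect_error(
    metabolic_model(
      tibble::tibble(id = "R1", stoichiometry = list(c(A = -1)),
                     lb = 5, ub = 1, genes = "", insertable = FALSE),
      metabolites = "A", objective = "R1"),
    "R1", class = "anaerodesign_model_error")
})

test_that("a minimal SBML document loads with fbc bounds and objective", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2">
  <model id="mini">
    <listOfParameters>
      <parameter id="lb_ex" value="-10" constant="true"/>
      <parameter id="zero" value="0" constant="true"/>
      <parameter id="ub" value="1000" constant="true"/>
    </listOfParameters>
    <listOfSpecies>
      <species id="A_e" compartment="e"/>
      <species id="A_c" compartment="c"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="EX_A" reversible="true" fbc:lowerFluxBound="lb_ex" fbc:upperFluxBound="ub">
        <listOfReactants><speciesReference species="A_e" stoichiometry="1"/></listOfReactants>
      </reaction>
      <reaction id="At" reversible="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub">
        <listOfReactants><speciesReference species="A_e" stoichiometry="1"/></listOfReactants>
        <listOfProducts><speciesReference species="A_c" stoichiometry="1"/></listOfProducts>
      </reaction>
      <reaction id="GROW" reversible="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub">
        <listOfReactants><speciesReference species="A_c" stoichiometry="1"/></listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj1">
      <fbc:objective fbc:id="obj1" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="GROW" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, path)
  model <- load_model(path)
  expect_equal(model$objective, "GROW")
  expect_equal(model$reactions$lb[model$reactions$id == "EX_A"], -10)
  sol <- fba(model)
  expect_equal(sol$objective, 10, tolerance = 1e-9)
})

test_that("FBA solves hand-checkable problems and respects its invariants", {
  # linear chain: uptake 10 caps the objective at 10
  chain <- metabolic_model(
    tibble::tibble(
      id = c("EX_A", "GROW"),
      stoichiometry = list(c(A = -1), c(A = -1)),
      lb = c(-10, 0), ub = c(1000, 1000),
      genes = "", insertable = FALSE),
    metabolites = "A", objective = "GROW")
  sol <- fba(chain)
  expect_equal(sol$objective, 10, tolerance = 1e-9)

  # all exchanges closed -> zero flux is optimal
  closed <- chain
  closed$reactions$lb[1] <- 0
  expect_equal(fba(closed)$objective, 0, tolerance = 1e-12)

  # optimal solutions satisfy steady state and bounds to 1e-9
  model <- anaerodesign:::apply_medium(toy_model(), toy_medium(TRUE))
  sol2 <- fba(model)
  S <- anaerodesign:::stoichiometry_matrix(model)
  v <- sol2$fluxes$flux
  expect_lt(max(abs(S %*% v)), 1e-8)
  expect_true(all(v >= model$reactions$lb - 1e-9))
  expect_true(all(v <= model$reactions$ub + 1e-9))
})

test_that("set_anoxic zeroes oxygen only, idempotently, and never helps growth", {
  med <- toy_medium(TRUE)
  ana <- set_anoxic(med)
  expect_equal(ana$max_uptake[ana$exchange_id == "EX_o2"], 0)
  expect_equal(ana$max_uptake[ana$exchange_id == "EX_carbon"], 6.14)
  expect_identical(set_anoxic(ana), ana)
  expect_error(set_anoxic(medium("EX_glc", 10)),
               class = "anaerodesign_config_error")

  # tightening a bound cannot increase the optimum
  model <- toy_model()
  expect_lte(fba(model, ana)$objective, fba(model, med)$objective + 1e-9)
})

test_that("enlarging an uptake bound never decreases the optimum", {
  withr::local_seed(97)
  med <- toy_medium(TRUE)
  base <- fba(toy_model(), med)$objective
  for (up in c(10, 50, 1000)) {
    med2 <- med
    med2$max_uptake[med2$exchange_id == "EX_carbon"] <- 6.14 + up
    expect_gte(fba(toy_model(), med2)$objective, base - 1e-9)
  }
})

test_that("LP optima match exhaustive vertex enumeration on small models", {
  withr::local_seed(61)
  n_checked <- 0
  for (i in 1:40) {
    prob <- random_small_model(n_met = sample(2:3, 1), n_rxn = sample(3:6, 1))
    lp <- anaerodesign:::solve_lp(prob$obj, prob$S, prob$lb, prob$ub)
    expect_equal(lp$status, "optimal")  # v = 0 always feasible
    oracle <- vertex_enumerate_max(prob$obj, prob$S, prob$lb, prob$ub)
    expect_equal(lp$objective, oracle, tolerance = 1e-6)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 40)
})

test_that("anoxia blocks energy and cofactor precursors but not central carbon", {
  model <- toy_model()
  med_ana <- set_anoxic(toy_medium(TRUE))
  blocked <- blocked_biomass_precursors(model, med_ana)
  expect_setequal(blocked$metabolite[blocked$blocked],
                  c("atp_c", "b12_c", "b6_c", "k2_c"))
  expect_false(blocked$blocked[blocked$metabolite == "prec_c"])

  # aerobic: nothing blocked
  blocked_aer <- blocked_biomass_precursors(model, toy_medium(TRUE))
  expect_false(any(blocked_aer$blocked))

  # with the denitrification set enabled the blocked set is exactly the
  # three oxygen-requiring cofactors
  den <- enable_insertable(model)
  blocked_den <- blocked_biomass_precursors(den, med_ana)
  expect_setequal(blocked_den$metabolite[blocked_den$blocked],
                  c("b12_c", "b6_c", "k2_c"))
})

test_that("oxygen tracing reports every single relieving change", {
  model <- toy_model()
  med_ana <- set_anoxic(toy_medium(TRUE))
  tr <- trace_oxygen_dependencies(model, med_ana, "b12_c")
  expect_true(any(tr$change == "relieve_oxygen_requirement" & tr$reaction == "B12S"))
  expect_true(any(tr$change == "open_exchange" & tr$reaction == "EX_b12"))
  expect_false(any(tr$reaction == "EX_b6"))  # the B6 route cannot make B12

  expect_error(trace_oxygen_dependencies(model, toy_medium(TRUE), "b12_c"),
               class = "anaerodesign_precondition_error")

  # a precursor with no single relieving change yields an empty report:
  # disable B12 synthesis and its transporter, so neither relieving the
  # oxygen requirement nor opening the exchange can deliver it
  crippled <- model
  crippled$reactions <- crippled$reactions[crippled$reactions$id != "B12t", ]
  crippled$reactions$ub[crippled$reactions$id == "B12S"] <- 0
  tr2 <- trace_oxygen_dependencies(crippled, med_ana, "b12_c")
  expect_equal(nrow(tr2), 0)
})

test_that("the unique minimal supplement set is the three vitamins", {
  model <- enable_insertable(toy_model())
  med_ana <- set_anoxic(toy_medium(TRUE))
  sets <- propose_media_supplements(model, med_ana,
                                    c("EX_b12", "EX_b6", "EX_k2"))
  expect_length(sets, 1)
  expect_setequal(sets[[1]], c("EX_b12", "EX_b6", "EX_k2"))

  # without denitrification the ATP gap remains: no vitamin subset works
  sets_none <- propose_media_supplements(toy_model(), med_ana,
                                         c("EX_b12", "EX_b6", "EX_k2"))
  expect_length(sets_none, 0)

  # empty candidate set -> empty result
  expect_length(propose_media_supplements(toy_model(), med_ana, character()), 0)

  # growing medium -> precondition error
  expect_error(propose_media_supplements(toy_model(), toy_medium(TRUE),
                                         "EX_b12"),
               class = "anaerodesign_precondition_error")
})

test_that("media files round-trip", {
  med <- toy_medium(TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_medium(med, path)
  expect_equal(tibble::as_tibble(read_medium(path)), tibble::as_tibble(med))
})
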