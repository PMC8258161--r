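test_that("a minimal one-reaction file parses to the expected model", {
  xml <- '<fluxml><reactionnetwork>
    <metabolitepools>
      <pool id="A" atoms="2" type="input"/>
      <pool id="B" atoms="2" type="output"/>
    </metabolitepools>
    <reaction id="v1"><reduct id="A" cx="ab"/><rproduct id="B" cx="ab"/></reaction>
  </reactionnetwork></fluxml>'
  m <- parse_model(xml)
  expect_equal(nrow(m$metabolites), 2)
  expect_length(m$reactions, 1)
  expect_equal(m$reactions[[1]]$id, "v1")
  expect_false(m$reactions[[1]]$bidirectional)
})

test_that("parse -> serialize -> parse is lossless for every fixture model", {
  for (name in c("chain", "branch", "clavam")) {
    fx <- get_fixture(name)
    path <- withr::local_tempfile(fileext = ".fml")
    write_model(fx$model, path)
    expect_equal(parse_model(path), fx$model, info = name)
  }
})

test_that("fixture files emitted to disk match the in-memory manifest", {
  dir <- withr::local_tempdir()
  fx <- make_branch_cycle(dir = dir)
  expect_true(all(file.exists(unlist(fx$files))))
  m2 <- parse_model(fx$files$model)
  expect_equal(m2, fx$model)
  cat2 <- parse_tracer_spec(fx$files$tracers, model = m2)
  expect_equal(cat2$species$price, fx$catalog$species$price)
  expect_equal(cat2$species$pattern, fx$catalog$species$pattern)
  manifest <- jsonlite::read_json(fx$files$manifest, simplifyVector = TRUE)
  expect_equal(manifest$free_net, fx$facts$free_net)
})

test_that("carbon imbalance and dangling references raise classed errors", {
  bad_balance <- '<fluxml><reactionnetwork>
    <metabolitepools>
      <pool id="A" atoms="3" type="input"/>
      <pool id="B" atoms="2" type="output"/>
    </metabolitepools>
    <reaction id="v1"><reduct id="A" cx="abc"/><rproduct id="B" cx="ab"/></reaction>
  </reactionnetwork></fluxml>'
  expect_error(parse_model(bad_balance), class = "fluxred_carbon_imbalance")

  dangling <- '<fluxml><reactionnetwork>
    <metabolitepools><pool id="A" atoms="1" type="input"/></metabolitepools>
    <reaction id="v1"><reduct id="A" cx="a"/><rproduct id="Z" cx="a"/></reaction>
  </reactionnetwork></fluxml>'
  expect_error(parse_model(dangling), class = "fluxred_dangling_ref")

  expect_error(parse_model("<fluxml><unclosed>"), class = "fluxred_xml_error")
  expect_error(parse_model("<notfluxml/>"), class = "fluxred_xml_error")
})

test_that("unsupported measurement types are rejected with a clear message", {
  xml <- '<fluxml><reactionnetwork>
    <metabolitepools>
      <pool id="A" atoms="1" type="input"/><pool id="B" atoms="1" type="output"/>
    </metabolitepools>
    <reaction id="v1"><reduct id="A" cx="a"/><rproduct id="B" cx="a"/></reaction>
  </reactionnetwork>
  <measurement><nmr id="x"/></measurement></fluxml>'
  expect_error(parse_model(xml), regexp = "unsupported measurement",
               class = "fluxred_xml_error")
})

test_that("tracer specs parse prices and reject invalid species", {
  cat <- get_fixture("clavam")$catalog
  sp <- cat$species
  expect_equal(sp$price[sp$substrate == "ARGx" & sp$label == "U-13C5"], 3449)
  expect_equal(sp$price[sp$substrate == "GLYCx" & sp$label == "12C"], 0.36)

  expect_error(tracer_catalog(list(substrates = list(list(id = "S", species = list())))),
               class = "fluxred_tracer_error")
  expect_error(tracer_catalog(list(substrates = list(list(id = "S", species = list(
    list(label = "x", pattern = 1, purity = 99, price = -1)))))),
    class = "fluxred_tracer_error")
  expect_error(tracer_catalog(list(substrates = list(list(id = "S", species = list(
    list(label = "x", pattern = 1, purity = 101, price = 1)))))),
    class = "fluxred_tracer_error")
  # substrate must be an input pool of the model
  expect_error(
    tracer_catalog(list(substrates = list(list(id = "M1", species = list(
      list(label = "x", pattern = c(1, 1), purity = 99, price = 1))))),
      model = get_fixture("chain")$model),
    class = "fluxred_tracer_error")
})

test_that("species isotopomer distributions follow per-position Bernoulli purity", {
  d <- species_isotopomer_distribution(c(1, 1, 1), purity = 100)
  expect_equal(d[8], 1)  # state 111
  d <- species_isotopomer_distribution(c(0, 1, 0), purity = 99)
  expect_equal(d[3], 0.99)  # state 010 (bit 1 set)
  expect_equal(d[1], 0.01)  # state 000
  d <- species_isotopomer_distribution(c(0, 0, 0))
  expect_equal(d[1], 1)
  # natural background puts mass on nominally unlabeled positions
  d <- species_isotopomer_distribution(c(0, 0), purity = 100, background = 1.07)
  expect_equal(d[1], (1 - 0.0107)^2)
})

test_that("species isotopomer distributions sum to 1 for random species", {
  withr::local_seed(42)
  for (i in 1:25) {
    n <- sample(1:6, 1)
    d <- species_isotopomer_distribution(sample(0:1, n, replace = TRUE),
                                         purity = runif(1, 50, 100),
                                         background = runif(1, 0, 5))
    expect_lt(abs(sum(d) - 1), 1e-12)
  }
})

test_that("mixtures must be simplex points per substrate", {
  expect_error(mixture(S = c(a = 0.5, b = 0.6)), class = "fluxred_mixture_error")
  expect_error(mixture(S = c(a = -0.1, b = 1.1)), class = "fluxred_mixture_error")
  mx <- mixture(S = c(a = 0.25, b = 0.75))
  expect_s3_class(mx, "tracer_mixture")
})

test_that("carbon conservation holds for every reaction in every fixture", {
  for (name in c("chain", "branch", "clavam")) {
    for (r in get_fixture(name)$model$reactions) {
      ea <- unlist(lapply(r$educts, `[[`, "atoms"))
      pa <- unlist(lapply(r$products, `[[`, "atoms"))
      expect_equal(sort(ea), sort(pa), info = paste(name, r$id))
    }
  }
})
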