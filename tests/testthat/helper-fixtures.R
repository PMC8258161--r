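# fixtures are deterministic; build once per test run
fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(name) {
  if (is.null(fixture_cache[[name]])) {
    fixture_cache[[name]] <- switch(name,
      chain = make_chain(3, 2),
      chain3c = make_chain(2, 3),
      branch = make_branch_cycle(),
      clavam = make_clavam_analog(),
      stop("unknown fixture ", name))
  }
  fixture_cache[[name]]
}

fixture_setup <- function(name) {
  key <- paste0(name, "_setup")
  if (is.null(fixture_cache[[key]])) {
    fx <- get_fixture(name)
    basis <- free_flux_basis(fx$model)
    poly <- build_polytope(basis, fx$model)
    sys <- emu_decompose(fx$model)
    fixture_cache[[key]] <- list(fx = fx, model = fx$model, catalog = fx$catalog,
                                 basis = basis, poly = poly, sys = sys)
  }
  fixture_cache[[key]]
}

# a random lattice-free mixture over a catalogue's substrates
random_mixture <- function(catalog) {
  subs <- unique(catalog$species$substrate)
  mx <- lapply(subs, function(s) {
    labs <- catalog$species$label[catalog$species$substrate == s]
    w <- runif(length(labs))
    setNames(w / sum(w), labs)
  })
  names(mx) <- subs
  mixture(mx)
}

# tiny two-substrate condensation model: C(2) = A(1) + B(1), C measured
condensation_model <- function() {
  mets <- tibble::tibble(id = c("Ax", "Bx", "A", "B", "C", "Co"),
                         n_carbons = c(1, 1, 1, 1, 2, 2),
                         role = c("input", "input", "balanced", "balanced",
                                  "balanced", "output"))
  rxns <- list(
    reaction("ua", list(list(met = "Ax", atoms = "a")),
             list(list(met = "A", atoms = "a"))),
    reaction("ub", list(list(met = "Bx", atoms = "a")),
             list(list(met = "B", atoms = "a"))),
    reaction("cond", list(list(met = "A", atoms = "a"),
                          list(met = "B", atoms = "b")),
             list(list(met = "C", atoms = c("a", "b")))),
    reaction("out", list(list(met = "C", atoms = c("a", "b"))),
             list(list(met = "Co", atoms = c("a", "b")))))
  network_model(mets, rxns,
                constraints = list(net_bounds = tibble::tibble(
                  flux = c("ua", "ub", "cond", "out"), lo = 0, hi = 100)),
                measurements = list(groups = tibble::tibble(
                  id = "frag_C", metabolite = "C",
                  positions = list(1:2), shifts = list(0:2))),
                name = "condensation")
}

condensation_catalog <- function() {
  tracer_catalog(list(substrates = list(
    list(id = "Ax", species = list(
      list(label = "L", pattern = 1, purity = 100, price = 10),
      list(label = "U0", pattern = 0, purity = 100, price = 1))),
    list(id = "Bx", species = list(
      list(label = "L", pattern = 1, purity = 100, price = 10),
      list(label = "U0", pattern = 0, purity = 100, price = 1))))))
}
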