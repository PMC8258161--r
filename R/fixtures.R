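#' Toy fixture: linear pathway
#'
#' `n_steps` pools in a row fed by one substrate, identity atom maps, one
#' terminal drain.  One free net flux; the terminal fragment's MID equals the
#' substrate MID for any mixture, and the labeling Jacobian is identically
#' zero (labeling depends on flux ratios only, and a chain has none).
#'
#' @param n_steps number of balanced pools (>= 1).
#' @param carbons carbons per pool.
#' @param dir optional directory; when given, the model XML, tracer YAML and
#'   manifest JSON are written there.
#' @return a `fixture_manifest`: list with `model`, `catalog`, `facts`, and
#'   (if written) `files`.
#' @export
make_chain <- function(n_steps = 3, carbons = 2, dir = NULL) {
  stopifnot(n_steps >= 1)
  atoms <- letters[seq_len(carbons)]
  mets <- tibble(id = c("S0", paste0("M", seq_len(n_steps)), "Mout"),
                 n_carbons = carbons,
                 role = c("input", rep("balanced", n_steps), "output"))
  pools <- c("S0", paste0("M", seq_len(n_steps)), "Mout")
  rxns <- lapply(seq_len(n_steps + 1), function(i) {
    reaction(paste0("v", i),
             educts = list(list(met = pools[i], atoms = atoms)),
             products = list(list(met = pools[i + 1], atoms = atoms)))
  })
  model <- network_model(
    mets, rxns,
    constraints = list(net_bounds = tibble(flux = paste0("v", seq_len(n_steps + 1)),
                                           lo = 0, hi = 100)),
    measurements = list(groups = tibble(
      id = "frag_end", metabolite = paste0("M", n_steps),
      positions = list(seq_len(carbons)), shifts = list(0:carbons))),
    name = "chain")
  catalog <- tracer_catalog(list(substrates = list(list(
    id = "S0", concentration = 10,
    species = list(
      list(label = "U", pattern = rep(1, carbons), purity = 100, price = 100),
      list(label = "12C", pattern = rep(0, carbons), purity = 100, price = 1))))))
  facts <- list(free_net = 1L, free_xch = 0L,
                terminal_fragment = "frag_end",
                terminal_mid_equals_substrate = TRUE,
                labeling_jacobian_zero = TRUE)
  finish_fixture("chain", model, catalog, facts, dir)
}

#' Toy fixture: branch / condensation motif with a scrambling exchange
#'
#' Two substrates (3- and 2-carbon).  The 3-carbon substrate is cleaved via
#' two routes that deliver *different* carbon pairs to a common 2-carbon
#' pool: directly, or after a carbon-permuting isomerase followed by a
#' bidirectional cleavage (the network's "cycle"); the pool then condenses
#' with the second substrate.  Three free fluxes result: the route split,
#' the second uptake, and the cleavage exchange (identifiable because the
#' back-reaction re-condenses two pools whose labeling mixes both routes).
#' With positionally informative tracers all three are identifiable; with
#' fully unlabeled feed the labeling rows of the FIM vanish and only the
#' rate-measured uptake survives — the fixture's built-in singular-design
#' example.
#'
#' @inheritParams make_chain
#' @export
make_branch_cycle <- function(dir = NULL) {
  mets <- tibble(
    id = c("SA", "SB", "A", "B", "C", "D", "E", "F", "Do", "Eo", "Co"),
    n_carbons = c(3, 2, 3, 2, 1, 2, 4, 3, 2, 4, 1),
    role = c("input", "input", rep("balanced", 6), rep("output", 3)))
  rxns <- list(
    reaction("upt_a", list(list(met = "SA", atoms = c("a", "b", "c"))),
             list(list(met = "A", atoms = c("a", "b", "c")))),
    reaction("upt_b", list(list(met = "SB", atoms = c("a", "b"))),
             list(list(met = "B", atoms = c("a", "b")))),
    reaction("cleave1", list(list(met = "A", atoms = c("a", "b", "c"))),
             list(list(met = "C", atoms = "a"),
                  list(met = "D", atoms = c("b", "c")))),
    # carbon-permuting isomerase: A(abc) -> F(cab)
    reaction("iso", list(list(met = "A", atoms = c("a", "b", "c"))),
             list(list(met = "F", atoms = c("c", "a", "b")))),
    # bidirectional cleavage: its back-reaction re-condenses C and D, whose
    # labeling mixes both routes, so the exchange flux is identifiable
    reaction("cleave2", list(list(met = "F", atoms = c("a", "b", "c"))),
             list(list(met = "C", atoms = "c"),
                  list(met = "D", atoms = c("a", "b"))),
             bidirectional = TRUE),
    reaction("cond", list(list(met = "D", atoms = c("a", "b")),
                          list(met = "B", atoms = c("c", "d"))),
             list(list(met = "E", atoms = c("a", "b", "c", "d")))),
    reaction("out_d", list(list(met = "D", atoms = c("a", "b"))),
             list(list(met = "Do", atoms = c("a", "b")))),
    reaction("out_e", list(list(met = "E", atoms = c("a", "b", "c", "d"))),
             list(list(met = "Eo", atoms = c("a", "b", "c", "d")))),
    reaction("out_c", list(list(met = "C", atoms = "a")),
             list(list(met = "Co", atoms = "a"))))
  rids <- vapply(rxns, `[[`, "", "id")
  model <- network_model(
    mets, rxns,
    constraints = list(
      # both routes must stay active (lower bound on the second cleavage);
      # with a vanishing route-2 flux its exchange would be meaningless and
      # the manifest's full-identifiability guarantee could not hold
      net_bounds = tibble(flux = rids, lo = ifelse(rids == "cleave2", 5, 0),
                          hi = 100),
      xch_bounds = tibble(flux = "cleave2", lo = 0, hi = 50)),
    measurements = list(
      groups = tibble(
        id = c("frag_E", "frag_D", "frag_C", "frag_F"),
        metabolite = c("E", "D", "C", "F"),
        positions = list(1:4, 1:2, 1L, 1:3),
        shifts = list(0:4, 0:2, 0:1, 0:3)),
      error_model = c(slope = 4.120e-2, intercept = 6.655e-3),
      rates = tibble(flux = "upt_b", value = 40, sd = 2),
      normalization = list(flux = "upt_a", value = 100)),
    name = "branch_cycle")
  catalog <- tracer_catalog(list(substrates = list(
    list(id = "SA", concentration = 10, species = list(
      list(label = "U-13C3", pattern = c(1, 1, 1), purity = 99, price = 640),
      list(label = "1-13C1", pattern = c(1, 0, 0), purity = 99, price = 250),
      list(label = "12C", pattern = c(0, 0, 0), purity = 100, price = 0.36))),
    list(id = "SB", concentration = 1, species = list(
      list(label = "U-13C2", pattern = c(1, 1), purity = 99, price = 1500),
      list(label = "12C", pattern = c(0, 0), purity = 100, price = 1))))),
    model = NULL)
  facts <- list(
    free_net = 2L, free_xch = 1L,
    degenerate_mixture = list(SA = c("12C" = 1), SB = c("12C" = 1)),
    informative_mixture = list(SA = c("1-13C1" = 1), SB = c("U-13C2" = 1)),
    max_nact_informative = 3L,
    max_nact_degenerate = 1L)
  finish_fixture("branch_cycle", model, catalog, facts, dir)
}

#' Reduced two-substrate central-metabolism analog
#'
#' A ~20-reaction, glycerol+arginine-style network sketching glycolysis, a
#' pentose-phosphate-like recycle, a TCA-like cycle with CO2-balanced
#' anaplerosis, amino-acid drains, and a condensation product pathway fusing
#' the 3-carbon and 5-carbon substrate backbones — structurally analogous to
#' a clavulanate-producer core model, deliberately *not* a parameter-faithful
#' reconstruction.  The tracer catalogue carries 4 + 3 species; the
#' unlabeled-glycerol (0.36 $/g) and fully labeled amino-acid (3,449 $/g)
#' prices are real market anchors, the remaining prices are synthetic
#' placeholders (flagged in the manifest).  Chemostat settings: 20 and
#' 0.17 g/L feed concentrations, dilution rate 0.03 1/h, 250 ml working
#' volume, sampling after 5 residence times.
#'
#' @inheritParams make_chain
#' @export
make_clavam_analog <- function(dir = NULL) {
  mets <- tibble(
    id = c("GLYCx", "ARGx",
           "GAP", "PYR", "H6", "P5", "ACA", "CIT", "AKG", "OAA", "GLU",
           "CO2", "CLAV",
           "CLAVo", "CO2o", "PYRo", "OAAo", "GLUo", "P5o"),
    n_carbons = c(3, 5, 3, 3, 6, 5, 2, 6, 5, 4, 5, 1, 8, 8, 1, 3, 4, 5, 5),
    role = c("input", "input", rep("balanced", 11), rep("output", 6)))
  A3 <- c("a", "b", "c"); A5 <- c("a", "b", "c", "d", "e")
  rxns <- list(
    reaction("glyc_in", list(list(met = "GLYCx", atoms = A3)),
             list(list(met = "GAP", atoms = A3))),
    reaction("arg_in", list(list(met = "ARGx", atoms = A5)),
             list(list(met = "GLU", atoms = A5))),
    reaction("emp1", list(list(met = "GAP", atoms = A3)),
             list(list(met = "PYR", atoms = A3))),
    reaction("ald", list(list(met = "GAP", atoms = A3),
                         list(met = "GAP", atoms = c("d", "e", "f"))),
             list(list(met = "H6", atoms = c("a", "b", "c", "d", "e", "f"))),
             bidirectional = TRUE),
    reaction("ppp1", list(list(met = "H6", atoms = c("a", "b", "c", "d", "e", "f"))),
             list(list(met = "P5", atoms = c("b", "c", "d", "e", "f")),
                  list(met = "CO2", atoms = "a"))),
    reaction("ppp2", list(list(met = "P5", atoms = A5)),
             list(list(met = "ACA", atoms = c("a", "b")),
                  list(met = "GAP", atoms = c("c", "d", "e")))),
    reaction("pdh", list(list(met = "PYR", atoms = A3)),
             list(list(met = "ACA", atoms = c("b", "c")),
                  list(met = "CO2", atoms = "a"))),
    reaction("tca1", list(list(met = "ACA", atoms = c("a", "b")),
                          list(met = "OAA", atoms = c("c", "d", "e", "f"))),
             list(list(met = "CIT", atoms = c("a", "b", "c", "d", "e", "f")))),
    reaction("tca2", list(list(met = "CIT", atoms = c("a", "b", "c", "d", "e", "f"))),
             list(list(met = "AKG", atoms = c("a", "b", "c", "d", "e")),
                  list(met = "CO2", atoms = "f"))),
    reaction("tca3", list(list(met = "AKG", atoms = A5)),
             list(list(met = "OAA", atoms = c("b", "c", "d", "e")),
                  list(met = "CO2", atoms = "a"))),
    reaction("ana", list(list(met = "PYR", atoms = A3),
                         list(met = "CO2", atoms = "d")),
             list(list(met = "OAA", atoms = c("a", "b", "c", "d"))),
             bidirectional = TRUE),
    reaction("glu_akg", list(list(met = "GLU", atoms = A5)),
             list(list(met = "AKG", atoms = A5)), bidirectional = TRUE),
    reaction("clav", list(list(met = "GAP", atoms = A3),
                          list(met = "GLU", atoms = c("d", "e", "f", "g", "h"))),
             list(list(met = "CLAV", atoms = c("a", "b", "c", "d", "e", "f", "g", "h")))),
    reaction("clav_out", list(list(met = "CLAV",
                                   atoms = c("a", "b", "c", "d", "e", "f", "g", "h"))),
             list(list(met = "CLAVo",
                       atoms = c("a", "b", "c", "d", "e", "f", "g", "h")))),
    reaction("co2_out", list(list(met = "CO2", atoms = "a")),
             list(list(met = "CO2o", atoms = "a"))),
    reaction("pyr_bm", list(list(met = "PYR", atoms = A3)),
             list(list(met = "PYRo", atoms = A3))),
    reaction("oaa_bm", list(list(met = "OAA", atoms = c("a", "b", "c", "d"))),
             list(list(met = "OAAo", atoms = c("a", "b", "c", "d")))),
    reaction("glu_bm", list(list(met = "GLU", atoms = A5)),
             list(list(met = "GLUo", atoms = A5))),
    reaction("p5_bm", list(list(met = "P5", atoms = A5)),
             list(list(met = "P5o", atoms = A5))))
  rids <- vapply(rxns, `[[`, "", "id")
  unidir_lo <- setNames(rep(0, length(rids)), rids)
  unidir_lo[c("ald", "ana", "glu_akg")] <- -100
  hi <- setNames(rep(100, length(rids)), rids)
  hi["arg_in"] <- 3  # arginine uptake below 3% of the normalized uptake
  model <- network_model(
    mets, rxns,
    constraints = list(
      net_bounds = tibble(flux = rids, lo = unname(unidir_lo), hi = unname(hi)),
      xch_bounds = tibble(flux = c("ald", "ana", "glu_akg"), lo = 0, hi = 200)),
    measurements = list(
      groups = tibble(
        id = c("ala_1_3", "asp_1_4", "asp_1_2", "glu_1_5", "glu_2_5",
               "p5aa_1_5", "clav_1_8"),
        metabolite = c("PYR", "OAA", "OAA", "GLU", "GLU", "P5", "CLAV"),
        positions = list(1:3, 1:4, 1:2, 1:5, 2:5, 1:5, 1:8),
        shifts = list(0:3, 0:4, 0:2, 0:5, 0:4, 0:5, 0:8)),
      error_model = c(slope = 4.120e-2, intercept = 6.655e-3),
      rates = tibble(flux = c("arg_in", "clav_out", "co2_out"),
                     value = c(2, 4, 80), sd = c(0.1, 0.2, 16)),
      normalization = list(flux = "glyc_in", value = 100)),
    name = "clavam_analog")
  catalog <- tracer_catalog(list(
    chemostat = list(dilution_rate = 0.03, working_volume = 0.25,
                     residence_times = 5),
    substrates = list(
      list(id = "GLYCx", concentration = 20, species = list(
        list(label = "U-13C3", pattern = c(1, 1, 1), purity = 99, price = 640),
        list(label = "1,3-13C2", pattern = c(1, 0, 1), purity = 99, price = 981),
        list(label = "2-13C1", pattern = c(0, 1, 0), purity = 99, price = 654),
        list(label = "12C", pattern = c(0, 0, 0), purity = 100, price = 0.36))),
      list(id = "ARGx", concentration = 0.17, species = list(
        list(label = "U-13C5", pattern = c(1, 1, 1, 1, 1), purity = 99, price = 3449),
        list(label = "5-13C1", pattern = c(0, 0, 0, 0, 1), purity = 99, price = 1176),
        list(label = "12C", pattern = c(0, 0, 0, 0, 0), purity = 100, price = 3))))))
  facts <- list(
    synthetic_prices = c("U-13C3", "1,3-13C2", "2-13C1", "5-13C1", "12C-ARG"),
    printed_prices = c("12C-GLYC" = 0.36, "U-13C5-ARG" = 3449),
    grid_total_10pct = 286 * 66,
    reference_mixture = list(GLYCx = c("2-13C1" = 1), ARGx = c("5-13C1" = 1)))
  finish_fixture("clavam_analog", model, catalog, facts, dir)
}

finish_fixture <- function(name, model, catalog, facts, dir) {
  out <- structure(list(name = name, model = model, catalog = catalog,
                        facts = facts), class = "fixture_manifest")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- list(model = file.path(dir, paste0(name, ".fml")),
                  tracers = file.path(dir, paste0(name, "_tracers.yml")),
                  manifest = file.path(dir, paste0(name, "_manifest.json")))
    write_model(model, files$model)
    write_tracer_yaml(catalog, files$tracers)
    jsonlite::write_json(facts, files$manifest, auto_unbox = TRUE, digits = NA)
    out$files <- files
  }
  out
}

write_tracer_yaml <- function(catalog, path) {
  subs <- lapply(unique(catalog$species$substrate), function(s) {
    sp <- catalog$species[catalog$species$substrate == s, ]
    list(id = s,
         concentration = unname(catalog$concentrations[[s]]),
         species = lapply(seq_len(nrow(sp)), function(i)
           list(label = sp$label[i], pattern = as.integer(sp$pattern[[i]]),
                purity = sp$purity[i], price = sp$price[i])))
  })
  yaml::write_yaml(list(chemostat = catalog$chemostat, substrates = subs), path)
  invisible(path)
}

#' @export
print.fixture_manifest <- function(x, ...) {
  cat(sprintf("<fixture_manifest '%s'>\n", x$name))
  print(x$model)
  invisible(x)
}
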