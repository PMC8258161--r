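#' Read a priced tracer catalogue
#'
#' The catalogue lists, per substrate, the commercially available isotopic
#' species with their positional 13C pattern, isotopic purity (atom%), and
#' price in $/g, together with the chemostat settings from which the required
#' substrate amounts are derived (medium concentration in g/L, dilution rate
#' in 1/h, working volume in L, and the number of reactor residence times
#' until sampling).  YAML is the native format; an XML rendering with the
#' same fields is accepted too.
#'
#' @param path path to a YAML (`.yml`/`.yaml`) or XML file.
#' @param model optional [network_model()]; if given, substrates are checked
#'   to be input pools of the model and patterns to match their carbon count.
#' @return a `tracer_catalog`: list with `species` (tibble `substrate`,
#'   `label`, `pattern` list-column of 0/1 per carbon, `purity`, `price`),
#'   `concentrations` (named g/L), and `chemostat`
#'   (`dilution_rate`, `working_volume`, `residence_times`).
#' @examples
#' path <- system.file("extdata", "example_tracers.yml", package = "fluxred")
#' cat <- parse_tracer_spec(path)
#' cat$species
#' @export
parse_tracer_spec <- function(path, model = NULL) {
  spec <- if (grepl("\\.(yml|yaml)$", path, ignore.case = TRUE) || !file.exists(path)) {
    yaml::read_yaml(path)
  } else {
    first <- readLines(path, n = 1L, warn = FALSE)
    if (grepl("^\\s*<", first)) parse_tracer_xml(path) else yaml::read_yaml(path)
  }
  tracer_catalog(spec, model = model)
}

parse_tracer_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort_fluxred(
                    paste0("malformed XML: ", conditionMessage(e)), "fluxred_xml_error"))
  ch <- xml2::xml_find_first(doc, "./chemostat")
  chem <- if (!inherits(ch, "xml_missing"))
    list(dilution_rate = as.numeric(xml2::xml_attr(ch, "dilution_rate")),
         working_volume = as.numeric(xml2::xml_attr(ch, "working_volume")),
         residence_times = as.numeric(xml2::xml_attr(ch, "residence_times")))
  else NULL
  subs <- lapply(xml2::xml_find_all(doc, "./substrate"), function(s) {
    list(id = xml2::xml_attr(s, "id"),
         concentration = as.numeric(xml2::xml_attr(s, "concentration")),
         species = lapply(xml2::xml_find_all(s, "./species"), function(sp) {
           list(label = xml2::xml_attr(sp, "label"),
                pattern = as.integer(strsplit(xml2::xml_attr(sp, "pattern"), "\\s+")[[1]]),
                purity = as.numeric(xml2::xml_attr(sp, "purity")),
                price = as.numeric(xml2::xml_attr(sp, "price")))
         }))
  })
  list(chemostat = chem, substrates = subs)
}

tracer_catalog <- function(spec, model = NULL) {
  if (is.null(spec$substrates) || length(spec$substrates) == 0)
    abort_fluxred("tracer spec declares no substrates", "fluxred_tracer_error")
  rows <- list()
  conc <- numeric(0)
  for (sub in spec$substrates) {
    if (length(sub$species) == 0)
      abort_fluxred(sprintf("substrate '%s' declares no tracer species", sub$id),
                    "fluxred_tracer_error")
    if (!is.null(model)) {
      role <- model$metabolites$role[match(sub$id, model$metabolites$id)]
      if (is.na(role) || role != "input")
        abort_fluxred(sprintf("substrate '%s' is not an input pool of the model", sub$id),
                      "fluxred_tracer_error")
    }
    for (sp in sub$species) {
      if (is.null(sp$price) || sp$price < 0)
        abort_fluxred(sprintf("species '%s' of '%s': price must be >= 0",
                              sp$label, sub$id), "fluxred_tracer_error")
      purity <- sp$purity %||% 100
      if (purity <= 0 || purity > 100)
        abort_fluxred(sprintf("species '%s' of '%s': purity must be in (0, 100]",
                              sp$label, sub$id), "fluxred_tracer_error")
      pattern <- as.numeric(unlist(sp$pattern))
      if (any(pattern < 0 | pattern > 1))
        abort_fluxred("labeling pattern entries must be 0/1", "fluxred_tracer_error")
      if (!is.null(model)) {
        nc <- model$metabolites$n_carbons[match(sub$id, model$metabolites$id)]
        if (length(pattern) != nc)
          abort_fluxred(sprintf("species '%s' of '%s': pattern length %d != %d carbons",
                                sp$label, sub$id, length(pattern), nc),
                        "fluxred_tracer_error")
      }
      rows[[length(rows) + 1L]] <- tibble(
        substrate = sub$id, label = sp$label, pattern = list(pattern),
        purity = purity, price = sp$price)
    }
    conc[sub$id] <- sub$concentration %||% NA_real_
  }
  structure(list(species = dplyr::bind_rows(rows),
                 concentrations = conc,
                 chemostat = spec$chemostat),
            class = "tracer_catalog")
}

#' @export
print.tracer_catalog <- function(x, ...) {
  cat("<tracer_catalog>\n")
  print(x$species)
  invisible(x)
}

#' Isotopomer distribution of one tracer species
#'
#' Converts a nominal positional labeling pattern plus an isotopic purity
#' into a probability distribution over all 2^n binary labeling states of the
#' substrate.  Each nominally labeled carbon is 13C with probability
#' `purity/100`, independently; each nominally unlabeled carbon is 13C with
#' probability `background/100` (0 by default; set 1.07 to include natural
#' 13C abundance).
#'
#' @param pattern numeric 0/1 vector, one entry per carbon (position 1 first).
#' @param purity atom% 13C at nominally labeled positions.
#' @param background atom% 13C at nominally unlabeled positions.
#' @return numeric vector of length `2^length(pattern)`; element `i`
#'   corresponds to the labeling state with binary expansion `i - 1`
#'   (bit `k - 1` set = carbon `k` is 13C).  Sums to 1.
#' @examples
#' species_isotopomer_distribution(c(0, 1, 0), purity = 99)
#' @export
species_isotopomer_distribution <- function(pattern, purity = 100, background = 0) {
  p13 <- ifelse(pattern >= 0.5, purity / 100, background / 100)
  n <- length(pattern)
  if (n == 0) return(1)
  out <- numeric(2^n)
  for (s in 0:(2^n - 1)) {
    bits <- bitwAnd(bitwShiftR(s, 0:(n - 1)), 1L)
    out[s + 1] <- prod(ifelse(bits == 1, p13, 1 - p13))
  }
  out
}

# isotopomer distribution of an input pool under a mixture of species
# fractions: named numeric (species label -> fraction) for this substrate
substrate_isotopomer_distribution <- function(catalog, substrate, fractions,
                                              background = 0) {
  sp <- catalog$species[catalog$species$substrate == substrate, ]
  if (nrow(sp) == 0)
    abort_fluxred(sprintf("no species for substrate '%s'", substrate),
                  "fluxred_tracer_error")
  bad <- setdiff(names(fractions), sp$label)
  if (length(bad) > 0)
    abort_fluxred(sprintf("unknown species '%s' for substrate '%s'", bad[1], substrate),
                  "fluxred_tracer_error")
  n <- length(sp$pattern[[1]])
  dist <- numeric(2^n)
  for (i in seq_len(nrow(sp))) {
    f <- if (sp$label[i] %in% names(fractions)) fractions[[sp$label[i]]] else 0
    if (f > 0)
      dist <- dist + f * species_isotopomer_distribution(sp$pattern[[i]],
                                                         sp$purity[i], background)
  }
  dist
}

#' Validate a tracer mixture
#'
#' A mixture assigns, per substrate, a fraction to every available species.
#' Fractions must be non-negative and sum to 1 per substrate.
#'
#' @param ... named arguments, one per substrate, each a named numeric vector
#'   of species fractions.
#' @return a named list of class `tracer_mixture`.
#' @examples
#' mixture(GLYC = c("2-13C1" = 0.8, "12C" = 0.2), ARG = c("U-13C6" = 1))
#' @export
mixture <- function(...) {
  mx <- list(...)
  if (length(mx) == 1 && is.list(mx[[1]]) && is.null(names(mx)[1])) mx <- mx[[1]]
  for (s in names(mx)) {
    fr <- mx[[s]]
    if (any(fr < 0))
      abort_fluxred(sprintf("negative fraction for substrate '%s'", s),
                    "fluxred_mixture_error")
    if (abs(sum(fr) - 1) > 1e-12)
      abort_fluxred(sprintf("fractions for substrate '%s' sum to %.15g, not 1",
                            s, sum(fr)), "fluxred_mixture_error")
  }
  structure(mx, class = "tracer_mixture")
}
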