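#' Read a 13C-MFA model from a FluxML-subset XML file
#'
#' The supported dialect is a documented subset of the FluxML flux modeling
#' language, covering exactly what the tracer-design workflow needs:
#' `<reactionnetwork>` with `<pool>` declarations and `<reaction>` elements
#' carrying letter-coded carbon atom transitions, `<constraints>` with net and
#' exchange bounds, fixed fluxes and general linear inequalities, and a
#' `<measurement>` section with GC-MS fragment groups, an affine error model,
#' rate measurements and an optional normalization flux.  An annotated
#' example ships in `system.file("extdata", "example_model.xml",
#' package = "fluxred")`.  NMR or isotopologue measurement types of full
#' FluxML are rejected with a clear message.
#'
#' Carbon positions are 1-based in files and in all user-facing tables.
#'
#' @param path path to an XML file, or a literal XML string.
#' @return a validated [network_model()].
#' @examples
#' xml <- '<fluxml><reactionnetwork>
#'   <metabolitepools>
#'     <pool id="A" atoms="2" type="input"/>
#'     <pool id="B" atoms="2" type="output"/>
#'   </metabolitepools>
#'   <reaction id="v1"><reduct id="A" cx="ab"/><rproduct id="B" cx="ab"/></reaction>
#' </reactionnetwork></fluxml>'
#' m <- parse_model(xml)
#' nrow(m$metabolites)
#' @export
parse_model <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort_fluxred(
                    paste0("malformed XML: ", conditionMessage(e)),
                    "fluxred_xml_error"))
  root <- doc
  if (xml2::xml_name(root) != "fluxml")
    abort_fluxred("root element must be <fluxml>", "fluxred_xml_error")
  rn <- xml2::xml_find_first(root, "./reactionnetwork")
  if (inherits(rn, "xml_missing"))
    abort_fluxred("missing required element <reactionnetwork>", "fluxred_xml_error")

  pools <- xml2::xml_find_all(rn, "./metabolitepools/pool")
  if (length(pools) == 0)
    abort_fluxred("missing required element <metabolitepools>/<pool>",
                  "fluxred_xml_error")
  metabolites <- tibble(
    id = xml2::xml_attr(pools, "id"),
    n_carbons = as.integer(xml2::xml_attr(pools, "atoms")),
    role = xml2::xml_attr(pools, "type", default = "balanced")
  )

  rx_nodes <- xml2::xml_find_all(rn, "./reaction")
  parse_side <- function(node, tag) {
    terms <- xml2::xml_find_all(node, paste0("./", tag))
    lapply(terms, function(t) {
      cx <- xml2::xml_attr(t, "cx", default = "")
      list(met = xml2::xml_attr(t, "id"),
           atoms = if (nzchar(cx)) strsplit(cx, "")[[1]] else character(0))
    })
  }
  reactions <- lapply(rx_nodes, function(node) {
    reaction(
      id = xml2::xml_attr(node, "id"),
      educts = parse_side(node, "reduct"),
      products = parse_side(node, "rproduct"),
      bidirectional = identical(xml2::xml_attr(node, "bidirectional"), "true")
    )
  })

  con <- list(
    net_bounds = parse_bounds(root, "./constraints/net/bound"),
    xch_bounds = parse_bounds(root, "./constraints/xch/bound"),
    fixed = {
      fx <- xml2::xml_find_all(root, "./constraints/net/fixed")
      tibble(flux = xml2::xml_attr(fx, "flux"),
             value = as.numeric(xml2::xml_attr(fx, "value")))
    },
    linear = parse_linear(root, vapply(reactions, `[[`, "", "id"))
  )

  meas <- xml2::xml_find_first(root, "./measurement")
  bad <- xml2::xml_find_all(root, ".//measurement/*[self::nmr or self::isotopologue or self::mimsgroup]")
  if (length(bad) > 0)
    abort_fluxred(sprintf("unsupported measurement type <%s>: only MS mass-isotopomer groups are supported",
                          xml2::xml_name(bad[[1]])), "fluxred_xml_error")
  groups <- xml2::xml_find_all(root, "./measurement/group")
  err <- xml2::xml_find_first(root, "./measurement/errormodel")
  rates <- xml2::xml_find_all(root, "./measurement/rate")
  normn <- xml2::xml_find_first(root, "./measurement/normalization")
  int_list <- function(x) lapply(strsplit(x, "\\s+"), as.integer)
  measurements <- list(
    groups = tibble(
      id = xml2::xml_attr(groups, "id"),
      metabolite = xml2::xml_attr(groups, "metabolite"),
      positions = int_list(xml2::xml_attr(groups, "positions")),
      shifts = if (length(groups))
        lapply(seq_along(groups), function(i) {
          s <- xml2::xml_attr(groups[[i]], "shifts")
          if (is.na(s)) 0:length(int_list(xml2::xml_attr(groups[[i]], "positions"))[[1]])
          else as.integer(strsplit(s, "\\s+")[[1]])
        }) else list()
    ),
    error_model = if (!inherits(err, "xml_missing"))
      c(slope = as.numeric(xml2::xml_attr(err, "slope")),
        intercept = as.numeric(xml2::xml_attr(err, "intercept"))) else NULL,
    rates = tibble(flux = xml2::xml_attr(rates, "flux"),
                   value = as.numeric(xml2::xml_attr(rates, "value")),
                   sd = as.numeric(xml2::xml_attr(rates, "stddev"))),
    normalization = if (!inherits(normn, "xml_missing"))
      list(flux = xml2::xml_attr(normn, "flux"),
           value = as.numeric(xml2::xml_attr(normn, "value"))) else NULL
  )
  name <- xml2::xml_attr(root, "name", default = "model")
  network_model(metabolites, reactions, con, measurements, name = name)
}

parse_bounds <- function(root, xpath) {
  b <- xml2::xml_find_all(root, xpath)
  if (length(b) == 0) return(NULL)
  tibble(flux = xml2::xml_attr(b, "flux"),
         lo = as.numeric(xml2::xml_attr(b, "lo")),
         hi = as.numeric(xml2::xml_attr(b, "hi")))
}

parse_linear <- function(root, rids) {
  lin <- xml2::xml_find_all(root, "./constraints/net/linear")
  if (length(lin) == 0) return(NULL)
  coef <- matrix(0, length(lin), length(rids), dimnames = list(NULL, rids))
  rhs <- numeric(length(lin))
  op <- character(length(lin))
  for (i in seq_along(lin)) {
    rhs[i] <- as.numeric(xml2::xml_attr(lin[[i]], "rhs"))
    op[i] <- xml2::xml_attr(lin[[i]], "op", default = "le")
    for (cf in xml2::xml_find_all(lin[[i]], "./coef")) {
      fl <- xml2::xml_attr(cf, "flux")
      if (!fl %in% rids)
        abort_fluxred(sprintf("linear constraint references unknown flux '%s'", fl),
                      "fluxred_dangling_ref")
      coef[i, fl] <- as.numeric(xml2::xml_attr(cf, "value"))
    }
  }
  list(coef = coef, rhs = rhs, op = op)
}

#' Serialize a network model back to FluxML-subset XML
#'
#' `parse_model(write_model(m, tempfile()))` reproduces `m` field by field;
#' the subset reader/writer pair is lossless for all supported elements.
#'
#' @param model a [network_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  doc <- xml2::xml_new_root("fluxml", name = model$name)
  rn <- xml2::xml_add_child(doc, "reactionnetwork")
  mp <- xml2::xml_add_child(rn, "metabolitepools")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    xml2::xml_add_child(mp, "pool", id = m$id, atoms = as.character(m$n_carbons),
                        type = m$role)
  }
  for (r in model$reactions) {
    node <- xml2::xml_add_child(rn, "reaction", id = r$id,
                                bidirectional = tolower(as.character(r$bidirectional)))
    for (e in r$educts)
      xml2::xml_add_child(node, "reduct", id = e$met, cx = paste(e$atoms, collapse = ""))
    for (p in r$products)
      xml2::xml_add_child(node, "rproduct", id = p$met, cx = paste(p$atoms, collapse = ""))
  }
  con <- xml2::xml_add_child(doc, "constraints")
  net <- xml2::xml_add_child(con, "net")
  nb <- model$constraints$net_bounds
  for (i in seq_len(nrow(nb)))
    xml2::xml_add_child(net, "bound", flux = nb$flux[i],
                        lo = format(nb$lo[i], digits = 17),
                        hi = format(nb$hi[i], digits = 17))
  fx <- model$constraints$fixed
  norm_flux <- model$measurements$normalization$flux %||% ""
  for (i in seq_len(nrow(fx)))
    if (fx$flux[i] != norm_flux)
      xml2::xml_add_child(net, "fixed", flux = fx$flux[i],
                          value = format(fx$value[i], digits = 17))
  lin <- model$constraints$linear
  if (!is.null(lin)) {
    for (i in seq_along(lin$rhs)) {
      ln <- xml2::xml_add_child(net, "linear",
                                rhs = format(lin$rhs[i], digits = 17), op = lin$op[i])
      nz <- which(lin$coef[i, ] != 0)
      for (j in nz)
        xml2::xml_add_child(ln, "coef", flux = colnames(lin$coef)[j],
                            value = format(lin$coef[i, j], digits = 17))
    }
  }
  xb <- model$constraints$xch_bounds
  xch <- xml2::xml_add_child(con, "xch")
  for (i in seq_len(nrow(xb)))
    xml2::xml_add_child(xch, "bound", flux = xb$flux[i],
                        lo = format(xb$lo[i], digits = 17),
                        hi = format(xb$hi[i], digits = 17))
  ms <- xml2::xml_add_child(doc, "measurement")
  gr <- model$measurements$groups
  for (i in seq_len(nrow(gr)))
    xml2::xml_add_child(ms, "group", id = gr$id[i], metabolite = gr$metabolite[i],
                        positions = paste(gr$positions[[i]], collapse = " "),
                        shifts = paste(gr$shifts[[i]], collapse = " "))
  em <- model$measurements$error_model
  xml2::xml_add_child(ms, "errormodel", slope = format(em[["slope"]], digits = 17),
                      intercept = format(em[["intercept"]], digits = 17))
  rt <- model$measurements$rates
  for (i in seq_len(nrow(rt)))
    xml2::xml_add_child(ms, "rate", flux = rt$flux[i],
                        value = format(rt$value[i], digits = 17),
                        stddev = format(rt$sd[i], digits = 17))
  if (!is.null(model$measurements$normalization)) {
    nz <- model$measurements$normalization
    xml2::xml_add_child(ms, "normalization", flux = nz$flux,
                        value = format(nz$value, digits = 17))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
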