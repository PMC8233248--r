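#' The ASCOT-Carer instrument definition
#'
#' The ASCOT-Carer (Adult Social Care Outcomes Toolkit for informal carers)
#' measures long-term-care-related quality of life of people caring for a
#' relative or friend across seven domains, each with four outcome levels
#' (1 = ideal state, 2 = no needs, 3 = some needs, 4 = high needs).
#' `ascot_carer_instrument()` returns the default instrument with the
#' published English statement wordings; alternative wordings (e.g. the
#' German version) can be loaded from a JSON file with
#' [read_instrument()].
#'
#' Two identification conventions travel with the instrument and are used by
#' the estimator: the reference item pinned to zero utility (`STS` level 4,
#' the state with the lowest perceived utility) and the aliased pair of items
#' estimated with a joint coefficient (`ENC` levels 1 and 2, whose valuations
#' are empirically indistinguishable).
#'
#' @return An object of class `bws_instrument`: a list with elements
#'   `domains` (named list of 7 domains, each with `code`, `label` and a
#'   character vector `statements` of length 4), `reference` (list with
#'   `domain`, `level`) and `joint` (list with `domain`, `levels`).
#' @examples
#' instr <- ascot_carer_instrument()
#' enumerate_levels(instr)
#' @export
ascot_carer_instrument <- function() {
  domains <- list(
    OCC = list(
      code = "OCC", label = "Occupation",
      statements = c(
        "I'm able to spend my time as I want, doing things I value or enjoy",
        "I'm able to do enough of the things I value or enjoy with my time",
        "I do some of the things I value or enjoy with my time, but not enough",
        "I don't do anything I value or enjoy with my time")),
    CTL = list(
      code = "CTL", label = "Control over daily life",
      statements = c(
        "I have as much control over my daily life as I want",
        "I have adequate control over my daily life",
        "I have some control over my daily life, but not enough",
        "I have no control over my daily life")),
    SELF = list(
      code = "SELF", label = "Looking after yourself",
      statements = c(
        "I look after myself as well as I want",
        "I look after myself well enough",
        "Sometimes I can't look after myself well enough",
        "I feel I am neglecting myself")),
    SAFE = list(
      code = "SAFE", label = "Personal safety",
      statements = c(
        "I feel as safe as I want",
        "Generally I feel adequately safe, but not as safe as I would like",
        "I feel less than adequately safe",
        "I don't feel at all safe")),
    SOC = list(
      code = "SOC", label = "Social participation and involvement",
      statements = c(
        "I have as much social contact as I want with people I like",
        "I have adequate social contact with people",
        "I have some social contact with people, but not enough",
        "I have little social contact with people and feel socially isolated")),
    STS = list(
      code = "STS", label = "Space and time to be yourself",
      statements = c(
        "I have all the space and time I need to be myself",
        "I have adequate space and time to be myself",
        "I have some of the space and time I need to be myself, but not enough",
        "I don't have any space or time to be myself")),
    ENC = list(
      code = "ENC", label = "Feeling supported and encouraged",
      statements = c(
        "I feel I have the encouragement and support I want",
        "I feel I have adequate encouragement and support",
        "I feel I have some encouragement and support, but not enough",
        "I feel I have no encouragement and support"))
  )
  new_instrument(domains,
                 reference = list(domain = "STS", level = 4L),
                 joint = list(domain = "ENC", levels = c(1L, 2L)))
}

#' Construct a best-worst instrument from its parts
#'
#' Low-level constructor used by [ascot_carer_instrument()] and
#' [read_instrument()]; validates the invariants (4 statements per domain,
#' unique codes, reference and joint items exist).
#'
#' @param domains named list; each element a list with `code`, `label`,
#'   `statements` (character vector of length 4).
#' @param reference list with `domain` (code) and `level` (1-4): the item
#'   whose utility is pinned to zero.
#' @param joint list with `domain` and `levels` (two levels sharing one
#'   coefficient), or `NULL` for no aliasing.
#' @return A `bws_instrument` object.
#' @export
new_instrument <- function(domains, reference, joint = NULL) {
  if (length(domains) < 1L) stop("instrument needs at least one domain")
  codes <- vapply(domains, function(d) d$code %||% NA_character_, character(1))
  if (anyNA(codes)) stop("every domain needs a 'code' field")
  if (anyDuplicated(codes)) {
    stop("duplicate domain codes: ", paste(codes[duplicated(codes)], collapse = ", "))
  }
  for (d in domains) {
    if (is.null(d$label)) stop("domain ", d$code, ": missing 'label'")
    if (length(d$statements) != 4L) {
      stop("domain ", d$code, ": expected exactly 4 statements, got ",
           length(d$statements))
    }
  }
  names(domains) <- codes
  check_item <- function(dom, lev, what) {
    if (!dom %in% codes) stop(what, " refers to unknown domain '", dom, "'")
    if (!all(lev %in% 1:4)) stop(what, " level out of range 1-4")
  }
  check_item(reference$domain, reference$level, "reference item")
  if (!is.null(joint)) {
    check_item(joint$domain, joint$levels, "joint-coefficient pair")
    if (length(joint$levels) != 2L || joint$levels[1] == joint$levels[2]) {
      stop("joint-coefficient pair must name two distinct levels")
    }
  }
  structure(list(domains = domains, reference = reference, joint = joint),
            class = "bws_instrument")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enumerate all attribute-levels of an instrument
#'
#' Lists every (domain, level) item in a fixed, stable order: domain-major in
#' instrument order, level ascending. The default ASCOT-Carer instrument has
#' 7 x 4 = 28 items. The `item_id` column is the canonical integer index used
#' throughout the package to address utility coefficients.
#'
#' @param instrument a `bws_instrument`.
#' @return data.frame with columns `item_id`, `domain`, `level`, `statement`.
#' @export
enumerate_levels <- function(instrument) {
  stopifnot(inherits(instrument, "bws_instrument"))
  codes <- names(instrument$domains)
  nd <- length(codes)
  data.frame(
    item_id = seq_len(4L * nd),
    domain = rep(codes, each = 4L),
    level = rep(1:4, nd),
    statement = unlist(lapply(instrument$domains, `[[`, "statements"),
                       use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' @rdname enumerate_levels
#' @export
n_items <- function(instrument) 4L * length(instrument$domains)

# item_id <-> (domain, level): domain-major then level-ascending
item_index <- function(instrument, domain, level) {
  di <- match(domain, names(instrument$domains))
  if (anyNA(di)) stop("unknown domain: ", paste(domain[is.na(di)], collapse = ", "))
  if (!all(level %in% 1:4)) stop("level out of range 1-4")
  (di - 1L) * 4L + as.integer(level)
}

#' Validate a carer quality-of-life state
#'
#' A state is a complete response profile: one level (1-4) for every domain
#' of the instrument, given as a named vector (names = domain codes).
#'
#' @param state named integer vector, one level per domain.
#' @param instrument a `bws_instrument`.
#' @return the state, as a named integer vector in instrument domain order,
#'   invisibly validated; errors name the offending domain.
#' @examples
#' instr <- ascot_carer_instrument()
#' validate_state(c(OCC = 1, CTL = 1, SELF = 1, SAFE = 1,
#'                  SOC = 1, STS = 1, ENC = 1), instr)
#' @export
validate_state <- function(state, instrument) {
  stopifnot(inherits(instrument, "bws_instrument"))
  codes <- names(instrument$domains)
  missing <- setdiff(codes, names(state))
  if (length(missing)) {
    stop("state is missing domain(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(state), codes)
  if (length(extra)) {
    stop("state has unknown domain(s): ", paste(extra, collapse = ", "))
  }
  st <- state[codes]
  bad <- codes[!(st %in% 1:4)]
  if (length(bad)) {
    stop("level out of range 1-4 for domain(s): ", paste(bad, collapse = ", "))
  }
  storage.mode(st) <- "integer"
  st
}

#' Read / write an instrument definition (JSON)
#'
#' The on-disk format is JSON with fields `domains` (array of objects with
#' `code`, `label`, `statements`), `reference` and `joint`. Round-trips are
#' lossless: statements are preserved byte-identically.
#'
#' @param path file path.
#' @param instrument a `bws_instrument`.
#' @return `read_instrument()` returns a `bws_instrument`;
#'   `write_instrument()` returns `path` invisibly.
#' @export
write_instrument <- function(instrument, path) {
  stopifnot(inherits(instrument, "bws_instrument"))
  obj <- list(
    domains = lapply(unname(instrument$domains), function(d)
      list(code = d$code, label = d$label, statements = d$statements)),
    reference = instrument$reference,
    joint = instrument$joint
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_instrument
#' @export
read_instrument <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  domains <- lapply(obj$domains, function(d)
    list(code = d$code, label = d$label,
         statements = vapply(d$statements, identity, character(1))))
  ref <- list(domain = obj$reference$domain, level = as.integer(obj$reference$level))
  joint <- if (!is.null(obj$joint)) {
    list(domain = obj$joint$domain,
         levels = vapply(obj$joint$levels, as.integer, integer(1)))
  }
  new_instrument(domains, reference = ref, joint = joint)
}

#' @export
print.bws_instrument <- function(x, ...) {
  cat("Best-worst scaling instrument:", length(x$domains), "domains x 4 levels (",
      n_items(x), "items )\n")
  for (d in x$domains) cat(sprintf("  %-5s %s\n", d$code, d$label))
  cat("reference item:", x$reference$domain, "level", x$reference$level, "\n")
  if (!is.null(x$joint)) {
    cat("joint coefficient:", x$joint$domain, "levels",
        paste(x$joint$levels, collapse = " & "), "\n")
  }
  invisible(x)
}
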