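# Reaction formula grammar:  "2 h_c + 0.5 o2_c -> h2o_c", "<->" = reversible.
# Omitted coefficient = 1. Left-hand side coefficients are stored negative.

#' Parse a reaction formula string
#'
#' @param formula a string in arrow syntax: substrate terms, `->` (irreversible)
#'   or `<->` (reversible), product terms; terms are `coef metabolite` with the
#'   coefficient optional (default 1). Either side may be empty (boundary
#'   reactions), not both.
#' @return list with `stoich` (named numeric, negative = consumed) and
#'   `reversible` (logical).
#' @examples
#' parse_reaction_formula("2 h_c + 0.5 o2_c -> h2o_c")
#' parse_reaction_formula("atp_c + thr__L_c <-> adp_c + thrp_c")
#' @export
parse_reaction_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  reversible <- grepl("<->", formula, fixed = TRUE)
  arrow <- if (reversible) "<->" else "->"
  if (!grepl(arrow, formula, fixed = TRUE))
    stop("formula parse error: no '->' or '<->' arrow in \"", formula, "\"")
  sides <- strsplit(formula, arrow, fixed = TRUE)[[1]]
  if (length(sides) > 2L)
    stop("formula parse error: multiple arrows in \"", formula, "\"")
  lhs <- parse_side(sides[1], "left", formula)
  rhs <- if (length(sides) == 2L) parse_side(sides[2], "right", formula) else numeric(0)
  if (length(lhs) == 0L && length(rhs) == 0L)
    stop("formula parse error: both sides empty in \"", formula, "\"")
  st <- c(-lhs, rhs)
  # metabolites appearing on both sides are netted; exact cancellation drops
  st <- tapply(st, names(st), sum)
  st <- setNames(as.numeric(st), names(st))
  st <- st[st != 0]
  list(stoich = st, reversible = reversible)
}

parse_side <- function(side, which, formula) {
  side <- trimws(side)
  if (!nzchar(side)) return(numeric(0))
  if (grepl("^\\+", side) || grepl("\\+$", side))
    stop("formula parse error: dangling '+' on the ", which, " side of \"",
         formula, "\"")
  terms <- strsplit(side, "+", fixed = TRUE)[[1]]
  coefs <- numeric(0)
  for (k in seq_along(terms)) {
    term <- trimws(terms[k])
    if (!nzchar(term))
      stop("formula parse error: dangling '+' at ", which, "-side term ", k,
           " of \"", formula, "\"")
    toks <- strsplit(term, "[[:space:]]+")[[1]]
    if (length(toks) == 1L) {
      coef <- 1; met <- toks[1]
    } else if (length(toks) == 2L) {
      coef <- suppressWarnings(as.numeric(toks[1]))
      if (is.na(coef))
        stop("formula parse error: unreadable coefficient '", toks[1],
             "' at ", which, "-side term ", k, " of \"", formula, "\"")
      met <- toks[2]
    } else {
      stop("formula parse error: unknown token in '", term, "' at ", which,
           "-side term ", k, " of \"", formula, "\"")
    }
    if (!grepl("^[A-Za-z0-9_]+$", met))
      stop("formula parse error: invalid metabolite id '", met, "' at ",
           which, "-side term ", k, " of \"", formula, "\"")
    if (met %in% names(coefs))
      stop("formula parse error: duplicate metabolite '", met, "' on the ",
           which, " side of \"", formula, "\"")
    coefs[met] <- coef
  }
  coefs
}

#' Render a reaction as a formula string
#' @param rxn a `reaction`.
#' @return a string in the arrow syntax accepted by [parse_reaction_formula()].
#' @export
format_reaction_formula <- function(rxn) {
  st <- rxn$stoich
  fmt <- function(v) {
    if (length(v) == 0L) return("")
    paste(ifelse(v == 1, names(v), paste(format(v, trim = TRUE), names(v))),
          collapse = " + ")
  }
  lhs <- -st[st < 0]; rhs <- st[st > 0]
  arrow <- if (rxn$lb < 0 && rxn$ub > 0) "<->" else "->"
  trimws(paste(fmt(lhs), arrow, fmt(rhs)))
}
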