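# Selection-expression language: a minimal VMD-like grammar.
#
#   expr     := or_expr
#   or_expr  := and_expr { "or" and_expr }
#   and_expr := not_expr { "and" not_expr }
#   not_expr := "not" not_expr | primary
#   primary  := "(" expr ")"
#             | "all"
#             | "name" word+ | "resname" word+ | "chain" word+
#             | "resid" range+ | "index" range+
#             | "within" number "of" primary
#   range    := integer | integer "-" integer      (e.g. "2-5", inclusive)
#
# `resid` matches the residue ids stored in the topology (taken verbatim
# from the source file); `index` is 0-based as in molecular viewers.
# `within r of X` selects every atom of the system whose (minimum-image,
# when a box is present) distance to any atom of X is <= r nm; the atoms of
# X are included in the result by default.

.SEL_KEYWORDS <- c("all", "name", "resname", "resid", "chain", "index",
                   "within", "of", "and", "or", "not")

.selTokenize <- function(expr) {
  if (!is.character(expr) || length(expr) != 1L || !nzchar(trimws(expr)))
    .stopData("selection parse error: empty expression")
  m <- gregexpr("\\(|\\)|[^()[:space:]]+", expr)[[1]]
  regmatches(expr, list(m))[[1]]
}

.selParseError <- function(st, what) {
  tok <- if (st$pos <= length(st$tokens)) sprintf("'%s'", st$tokens[st$pos]) else "end of expression"
  .stopData(sprintf("selection parse error at token %d (%s): %s", st$pos, tok, what))
}

.selPeek <- function(st) if (st$pos <= length(st$tokens)) st$tokens[st$pos] else NA_character_
.selNext <- function(st) { t <- .selPeek(st); st$pos <- st$pos + 1L; t }

.selParse <- function(expr) {
  st <- new.env()
  st$tokens <- .selTokenize(expr)
  st$pos <- 1L
  ast <- .selParseOr(st)
  if (st$pos <= length(st$tokens)) .selParseError(st, "unexpected trailing input")
  ast
}

.selParseOr <- function(st) {
  left <- .selParseAnd(st)
  while (identical(.selPeek(st), "or")) {
    .selNext(st)
    left <- list(op = "or", a = left, b = .selParseAnd(st))
  }
  left
}

.selParseAnd <- function(st) {
  left <- .selParseNot(st)
  while (identical(.selPeek(st), "and")) {
    .selNext(st)
    left <- list(op = "and", a = left, b = .selParseNot(st))
  }
  left
}

.selParseNot <- function(st) {
  if (identical(.selPeek(st), "not")) {
    .selNext(st)
    return(list(op = "not", a = .selParseNot(st)))
  }
  .selParsePrimary(st)
}

.selParseValues <- function(st) {
  vals <- character(0)
  repeat {
    t <- .selPeek(st)
    if (is.na(t) || t %in% .SEL_KEYWORDS || t %in% c("(", ")")) break
    vals <- c(vals, .selNext(st))
  }
  if (length(vals) == 0L) .selParseError(st, "expected at least one value")
  vals
}

.selParseRanges <- function(st) {
  vals <- .selParseValues(st)
  lapply(vals, function(v) {
    if (grepl("^[0-9]+$", v)) {
      i <- as.integer(v); c(i, i)
    } else if (grepl("^[0-9]+-[0-9]+$", v)) {
      p <- as.integer(strsplit(v, "-", fixed = TRUE)[[1]])
      if (p[1] > p[2]) .stopData(sprintf("selection parse error: empty range '%s'", v))
      p
    } else {
      .stopData(sprintf("selection parse error: '%s' is not an integer or range", v))
    }
  })
}

.selParsePrimary <- function(st) {
  t <- .selNext(st)
  if (is.na(t)) .selParseError(st, "expected an expression")
  if (t == "(") {
    inner <- .selParseOr(st)
    if (!identical(.selNext(st), ")")) .selParseError(st, "expected ')'")
    return(inner)
  }
  switch(t,
    all = list(op = "all"),
    name = list(op = "name", values = .selParseValues(st)),
    resname = list(op = "resname", values = .selParseValues(st)),
    chain = list(op = "chain", values = .selParseValues(st)),
    resid = list(op = "resid", ranges = .selParseRanges(st)),
    index = list(op = "index", ranges = .selParseRanges(st)),
    within = {
      r <- suppressWarnings(as.numeric(.selNext(st)))
      if (is.na(r) || r <= 0) .selParseError(st, "'within' needs a positive distance in nm")
      if (!identical(.selNext(st), "of")) .selParseError(st, "expected 'of' after 'within <r>'")
      list(op = "within", r = r, a = .selParsePrimary(st))
    },
    .selParseError(structure(list(pos = st$pos - 1L, tokens = st$tokens), class = "list"),
                   sprintf("unknown keyword '%s'", t))
  )
}

.inRanges <- function(values, ranges) {
  hit <- rep(FALSE, length(values))
  for (r in ranges) hit <- hit | (values >= r[1] & values <= r[2])
  hit
}

# Evaluate an AST against the full atom table; returns a logical mask.
.selEval <- function(ast, atomsDf, xyz, boxObj, withinIncludesSelf = TRUE) {
  n <- nrow(atomsDf)
  switch(ast$op,
    all = rep(TRUE, n),
    name = atomsDf$name %in% ast$values,
    resname = atomsDf$resname %in% ast$values,
    chain = atomsDf$chain %in% ast$values,
    resid = .inRanges(atomsDf$resid, ast$ranges),
    index = .inRanges(seq_len(n) - 1L, ast$ranges),
    and = .selEval(ast$a, atomsDf, xyz, boxObj, withinIncludesSelf) &
          .selEval(ast$b, atomsDf, xyz, boxObj, withinIncludesSelf),
    or = .selEval(ast$a, atomsDf, xyz, boxObj, withinIncludesSelf) |
         .selEval(ast$b, atomsDf, xyz, boxObj, withinIncludesSelf),
    not = !.selEval(ast$a, atomsDf, xyz, boxObj, withinIncludesSelf),
    within = {
      innerMask <- .selEval(ast$a, atomsDf, xyz, boxObj, withinIncludesSelf)
      q <- which(innerMask)
      mask <- rep(FALSE, n)
      if (length(q)) {
        hits <- searchWithin(xyz, q, ast$r, box = boxObj,
                             includeQuery = withinIncludesSelf)
        mask[hits] <- TRUE
      }
      mask
    },
    .stopData(sprintf("selection evaluator: unknown node '%s'", ast$op))
  )
}
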