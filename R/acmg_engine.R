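# ACMG-AMP evidence-combining engine: parse evidence-code strings and combine
# them into the five-tier verdict (pathogenic / likely_pathogenic / vus /
# likely_benign / benign) per the 2015 guideline's combining criteria.

EVIDENCE_CODES <- c(
  "PVS1",
  paste0("PS", 1:4),
  paste0("PM", 1:6),
  paste0("PP", 1:5),
  "BA1",
  paste0("BS", 1:4),
  paste0("BP", 1:7)
)

VERDICTS <- c("pathogenic", "likely_pathogenic", "vus", "likely_benign", "benign")

strength_class <- function(codes) {
  cls <- character(length(codes))
  cls[codes == "PVS1"] <- "pvs"
  cls[startsWith(codes, "PS")] <- "ps"
  cls[startsWith(codes, "PM")] <- "pm"
  cls[startsWith(codes, "PP")] <- "pp"
  cls[codes == "BA1"] <- "ba"
  cls[startsWith(codes, "BS")] <- "bs"
  cls[startsWith(codes, "BP")] <- "bp"
  cls
}

#' Parse an evidence-code string into a code set
#'
#' Accepts whitespace- or comma-separated ACMG-AMP code lists (for example
#' `"PVS1 PM1 PM2 PP5"` or `"PS3,PM2,PP3"`). Parsing is case-insensitive
#' and duplicates collapse; an empty or `NA` string yields the empty set.
#'
#' @param text A single code-list string.
#' @return Character vector of canonical codes (possibly empty).
#' @examples
#' parse_evidence("PVS1 PM1 PM2 PP5 BS2")
#' @export
parse_evidence <- function(text) {
  if (length(text) != 1L) abort_validation("parse_evidence takes a single string")
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  tokens <- toupper(strsplit(trimws(text), "[,;[:space:]]+")[[1]])
  tokens <- tokens[nzchar(tokens)]
  unknown <- setdiff(tokens, EVIDENCE_CODES)
  if (length(unknown)) {
    abort_validation(sprintf("unknown evidence code(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  unique(tokens)
}

# Combining rules, evaluated on per-class multiplicities
# (nvs/ns/nm/np = pathogenic-side counts; ba/nbs/nbp = benign-side counts).
# Rule labels are stable for auditability; order encodes precedence within
# a verdict (the first rule to fire is reported).
path_rules <- list(
  P1a = function(v) v["pvs"] >= 1 && v["ps"] >= 1,
  P1b = function(v) v["pvs"] >= 1 && v["pm"] >= 2,
  P1c = function(v) v["pvs"] >= 1 && v["pm"] == 1 && v["pp"] >= 1,
  P1d = function(v) v["pvs"] >= 1 && v["pp"] >= 2,
  P2  = function(v) v["ps"] >= 2,
  P3a = function(v) v["ps"] == 1 && v["pm"] >= 3,
  P3b = function(v) v["ps"] == 1 && v["pm"] == 2 && v["pp"] >= 2,
  P3c = function(v) v["ps"] == 1 && v["pm"] == 1 && v["pp"] >= 4
)

lp_rules <- list(
  LP1 = function(v) v["pvs"] >= 1 && v["pm"] == 1,
  LP2 = function(v) v["ps"] == 1 && v["pm"] >= 1 && v["pm"] <= 2,
  LP3 = function(v) v["ps"] == 1 && v["pp"] >= 2,
  LP4 = function(v) v["pm"] >= 3,
  LP5 = function(v) v["pm"] == 2 && v["pp"] >= 2,
  LP6 = function(v) v["pm"] == 1 && v["pp"] >= 4
)

benign_rules <- list(
  B1 = function(v) v["ba"] >= 1,
  B2 = function(v) v["bs"] >= 2
)

lb_rules <- list(
  LB1 = function(v) v["bs"] == 1 && v["bp"] >= 1,
  LB2 = function(v) v["bp"] >= 2
)

first_firing <- function(rules, v) {
  for (nm in names(rules)) {
    if (isTRUE(rules[[nm]](v))) return(nm)
  }
  NA_character_
}

#' Combine an evidence set into a five-tier classification
#'
#' Evaluates the guideline combining criteria on the evidence multiset and
#' returns the verdict together with the label of the rule that fired.
#' Pathogenic-side and benign-side combinations are evaluated independently;
#' when combinations fire on both sides the evidence is contradictory and
#' the verdict is `vus` (`conflict_mode = "combination"`, the default).
#' Lone benign-side codes that complete no benign combination do not force
#' a conflict. In `conflict_mode = "strict"` the verdict is unchanged but
#' the fired rule is flagged `+conflict` whenever codes from both sides
#' co-occur, for sensitivity analysis.
#'
#' @param codes Character vector of evidence codes (as from
#'   [parse_evidence()]), or a single unparsed string.
#' @param conflict_mode `"combination"` (default) or `"strict"`.
#' @return One-row tibble with columns `verdict` and `fired_rule`.
#' @examples
#' classify_evidence(c("PVS1", "PM1", "PM2")) # pathogenic
#' classify_evidence("PVS1 PM2") # likely_pathogenic
#' @export
classify_evidence <- function(codes, conflict_mode = c("combination", "strict")) {
  conflict_mode <- match.arg(conflict_mode)
  if (is.character(codes) && length(codes) == 1L && !codes[1] %in% EVIDENCE_CODES) {
    codes <- parse_evidence(codes)
  }
  codes <- unique(toupper(codes))
  unknown <- setdiff(codes, EVIDENCE_CODES)
  if (length(unknown)) {
    abort_validation(sprintf("unknown evidence code(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  cls <- strength_class(codes)
  v <- c(pvs = sum(cls == "pvs"), ps = sum(cls == "ps"), pm = sum(cls == "pm"),
         pp = sum(cls == "pp"), ba = sum(cls == "ba"), bs = sum(cls == "bs"),
         bp = sum(cls == "bp"))

  p_rule <- first_firing(path_rules, v)
  lp_rule <- first_firing(lp_rules, v)
  b_rule <- first_firing(benign_rules, v)
  lb_rule <- first_firing(lb_rules, v)

  path_fires <- !is.na(p_rule) || !is.na(lp_rule)
  benign_fires <- !is.na(b_rule) || !is.na(lb_rule)

  if (path_fires && benign_fires) {
    verdict <- "vus"
    rule <- "conflict_both_sides"
  } else if (path_fires) {
    verdict <- if (!is.na(p_rule)) "pathogenic" else "likely_pathogenic"
    rule <- if (!is.na(p_rule)) p_rule else lp_rule
  } else if (benign_fires) {
    verdict <- if (!is.na(b_rule)) "benign" else "likely_benign"
    rule <- if (!is.na(b_rule)) b_rule else lb_rule
  } else {
    verdict <- "vus"
    rule <- "default_vus"
  }

  both_sides_present <- (v["pvs"] + v["ps"] + v["pm"] + v["pp"]) > 0 &&
    (v["ba"] + v["bs"] + v["bp"]) > 0
  if (conflict_mode == "strict" && both_sides_present &&
      rule != "conflict_both_sides") {
    rule <- paste0(rule, "+conflict")
  }
  tibble(verdict = verdict, fired_rule = rule)
}

#' Check a table of evidence sets against recorded conclusions
#'
#' Classifies each row's evidence string and compares the verdict with the
#' recorded conclusion, returning per-row agreement and the overall
#' concordant count.
#'
#' @param rows Tibble with columns `evidence_codes` (code-list strings) and
#'   `assertion` (expected verdict token); extra columns are carried through.
#' @param conflict_mode Passed to [classify_evidence()].
#' @return A tibble of class `sf_concordance`: the input rows plus `verdict`,
#'   `fired_rule` and logical `concordant`, with attributes `n_concordant`
#'   and `n_discordant`.
#' @export
verify_table <- function(rows, conflict_mode = "combination") {
  rows <- as_tibble(rows)
  if (nrow(rows) == 0L) {
    out <- rows
    out$verdict <- character()
    out$fired_rule <- character()
    out$concordant <- logical()
  } else {
    res <- bind_rows(map(rows$evidence_codes, classify_evidence,
                         conflict_mode = conflict_mode))
    out <- bind_cols(rows, res)
    out$concordant <- out$verdict == out$assertion
  }
  structure(out,
            n_concordant = sum(out$concordant),
            n_discordant = sum(!out$concordant),
            class = c("sf_concordance", class(out)))
}

#' @export
print.sf_concordance <- function(x, ...) {
  cat(sprintf("<sf_concordance> %d/%d concordant\n",
              attr(x, "n_concordant"), nrow(x)))
  NextMethod()
}
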