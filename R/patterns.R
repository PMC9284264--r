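# Expression-pattern classification for F1 hybrids vs their parents.
#
# Each homolog pair, per stage and per hybrid, carries three ternary
# differential-expression calls:
#   hb : second parent (GB) vs first parent (GH); "up" = GB higher
#   fh : hybrid vs GH;                            "up" = hybrid higher
#   fb : hybrid vs GB;                            "up" = hybrid higher
# The classifier maps the 27 call combinations onto 12 Roman-numeral bins,
# a "conserved" outcome (no differences anywhere), or "ambiguous"
# (internally inconsistent call combinations). Bins collapse onto five
# biological categories: additivity, expression-level dominance toward
# either parent (ELD-H / ELD-B), and transgressive up/down-regulation
# (TUR / TDR) -- the expression signature of overdominance.

.call_levels <- c("up", "down", "ns")

.bin_levels <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX",
                 "X", "XI", "XII", "conserved", "ambiguous")

.category_levels <- c("Additive", "ELD-H", "ELD-B", "TUR", "TDR", "none")

# Canonical decision table: one row per reachable Roman-numeral bin plus
# the conserved outcome. Everything else is ambiguous.
.bin_table <- data.frame(
  bin = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X",
          "XI", "XII", "conserved"),
  hb  = c("up",   "up",   "up",   "down", "ns",   "up",   "ns",   "down",
          "up",   "down", "down", "down", "ns"),
  fh  = c("up",   "up",   "down", "ns",   "up",   "up",   "down", "up",
          "ns",   "down", "down", "down", "ns"),
  fb  = c("down", "ns",   "down", "up",   "up",   "up",   "down", "up",
          "down", "down", "ns",   "up",   "ns"),
  stringsAsFactors = FALSE
)

.bin_category <- c(
  I = "Additive", XII = "Additive",
  IV = "ELD-H", IX = "ELD-H",
  II = "ELD-B", XI = "ELD-B",
  V = "TUR", VI = "TUR", VIII = "TUR",
  III = "TDR", VII = "TDR", X = "TDR",
  conserved = "none", ambiguous = "none"
)

.check_calls <- function(x, name) {
  x <- as.character(x)
  bad <- !x %in% .call_levels
  if (any(bad)) {
    stop_hybex(sprintf("%s contains invalid call(s): %s", name,
                       paste(unique(x[bad]), collapse = ", ")),
               "invalid_input")
  }
  x
}

#' Classify hybrid expression patterns from three ternary DE calls
#'
#' Maps each combination of the three pairwise differential-expression calls
#' (parent-vs-parent, hybrid-vs-parent-1, hybrid-vs-parent-2) onto one of the
#' twelve Roman-numeral expression-pattern bins, or `"conserved"` when no
#' comparison is significant, or `"ambiguous"` for internally inconsistent
#' combinations (for example, parents differing while the hybrid differs from
#' neither). The function is total: every input combination yields exactly
#' one outcome.
#'
#' @param hb ternary call for parent 2 (GB) vs parent 1 (GH); `"up"` means
#'   GB is higher.
#' @param fh ternary call for hybrid vs GH; `"up"` means the hybrid is higher.
#' @param fb ternary call for hybrid vs GB; `"up"` means the hybrid is higher.
#' @return character vector of bins (`"I"`..`"XII"`, `"conserved"`,
#'   `"ambiguous"`), recycled to the common length of the inputs.
#' @examples
#' classify_bins("up", "up", "up")    # transgressive up-regulation, bin VI
#' classify_bins("ns", "ns", "ns")    # conserved
#' @export
classify_bins <- function(hb, fh, fb) {
  n <- max(length(hb), length(fh), length(fb))
  hb <- rep_len(.check_calls(hb, "hb"), n)
  fh <- rep_len(.check_calls(fh, "fh"), n)
  fb <- rep_len(.check_calls(fb, "fb"), n)
  key <- paste(hb, fh, fb, sep = "|")
  table_key <- paste(.bin_table$hb, .bin_table$fh, .bin_table$fb, sep = "|")
  out <- .bin_table$bin[match(key, table_key)]
  out[is.na(out)] <- "ambiguous"
  out
}

#' Collapse a pattern bin to its five-way category
#'
#' Fixed mapping: bins I and XII are additivity; IV and IX are
#' expression-level dominance toward the GH parent (ELD-H); II and XI are
#' dominance toward the GB parent (ELD-B); V, VI and VIII are transgressive
#' up-regulation (TUR); III, VII and X are transgressive down-regulation
#' (TDR). `conserved` and `ambiguous` map to `"none"`.
#'
#' @param bin character vector of bins as returned by [classify_bins()].
#' @return character vector of categories.
#' @export
bin_to_category <- function(bin) {
  bin <- as.character(bin)
  bad <- !bin %in% .bin_levels
  if (any(bad)) {
    stop_hybex(sprintf("unknown bin(s): %s",
                       paste(unique(bin[bad]), collapse = ", ")),
               "invalid_input")
  }
  unname(.bin_category[bin])
}

#' Classify homolog pairs from three differential-expression tables
#'
#' Joins the three per-pair DE call tables (as produced by [de_table()]) on
#' `pair_id` and produces one pattern call per pair.
#'
#' @param de_hb DE results for GB vs GH (GH is group a).
#' @param de_fh DE results for hybrid vs GH (GH is group a).
#' @param de_fb DE results for hybrid vs GB (GB is group a).
#' @param stage optional stage label recorded in the output.
#' @param hybrid optional hybrid label recorded in the output.
#' @return data frame with columns `pair_id`, `stage`, `hybrid`, `call_hb`,
#'   `call_fh`, `call_fb`, `bin`, `category`.
#' @export
classify_pairs <- function(de_hb, de_fh, de_fb, stage = NA_character_,
                           hybrid = NA_character_) {
  ids <- de_hb$pair_id
  if (!identical(ids, de_fh$pair_id) || !identical(ids, de_fb$pair_id)) {
    fh <- de_fh[match(ids, de_fh$pair_id), ]
    fb <- de_fb[match(ids, de_fb$pair_id), ]
    if (anyNA(fh$pair_id) || anyNA(fb$pair_id)) {
      stop_hybex("DE tables do not cover the same pair ids", "inconsistent_input")
    }
    de_fh <- fh; de_fb <- fb
  }
  bin <- classify_bins(de_hb$call, de_fh$call, de_fb$call)
  data.frame(
    pair_id = ids, stage = stage, hybrid = hybrid,
    call_hb = de_hb$call, call_fh = de_fh$call, call_fb = de_fb$call,
    bin = bin, category = bin_to_category(bin),
    stringsAsFactors = FALSE
  )
}

#' Per-bin and per-category pattern proportions
#'
#' Summarises a set of pattern calls into percentages, mirroring the
#' proportion panels of a pattern-classification figure. By default the
#' denominator is the number of pairs assigned a Roman-numeral bin
#' (conserved and ambiguous pairs excluded); with `denominator = "all"`
#' every call counts.
#'
#' @param calls data frame of pattern calls from [classify_pairs()].
#' @param denominator `"binned"` (default) or `"all"`.
#' @return list with data frames `by_bin` and `by_category`, each with
#'   columns `count` and `percent`, plus the `denominator` size `n`.
#' @export
pattern_proportions <- function(calls, denominator = c("binned", "all")) {
  denominator <- match.arg(denominator)
  if (is.null(calls) || nrow(calls) == 0L) {
    stop_hybex("empty pattern-call input", "empty_input")
  }
  roman <- setdiff(.bin_levels, c("conserved", "ambiguous"))
  binned <- calls[calls$bin %in% roman, , drop = FALSE]
  n <- if (denominator == "binned") nrow(binned) else nrow(calls)
  bin_counts <- table(factor(binned$bin, levels = roman))
  cat_counts <- table(factor(binned$category,
                             levels = setdiff(.category_levels, "none")))
  pct <- function(k) if (n > 0) 100 * as.numeric(k) / n else rep(0, length(k))
  list(
    by_bin = data.frame(bin = names(bin_counts),
                        count = as.integer(bin_counts),
                        percent = pct(bin_counts),
                        stringsAsFactors = FALSE),
    by_category = data.frame(category = names(cat_counts),
                             count = as.integer(cat_counts),
                             percent = pct(cat_counts),
                             stringsAsFactors = FALSE),
    n = n
  )
}

#' Three-set stage intersection (Venn regions)
#'
#' Partitions the union of three per-stage gene-id sets into the seven
#' disjoint Venn regions, e.g. to count genes transgressively regulated at
#' one, two or all three seedling stages.
#'
#' @param sets named list of exactly three character vectors of ids.
#' @return data frame with one row per region: logical membership columns
#'   (one per set name), `region` (e.g. `"110"`), and `count`. The region
#'   counts sum to the size of the union; region `"111"` is the triple
#'   intersection.
#' @export
stage_intersections <- function(sets) {
  if (!is.list(sets) || length(sets) != 3L) {
    stop_hybex("exactly three stage sets are required", "invalid_input")
  }
  nm <- names(sets) %||% paste0("set", 1:3)
  if (is.null(names(sets)) || any(names(sets) == "")) names(sets) <- nm
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 0L) member <- matrix(logical(0), 0, 3)
  combos <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                        c = c(TRUE, FALSE))
  combos <- combos[rowSums(combos) > 0, ]
  counts <- apply(combos, 1L, function(row) {
    sum(member[, 1] == row[1] & member[, 2] == row[2] & member[, 3] == row[3])
  })
  out <- data.frame(combos, region = apply(combos, 1L, function(r)
    paste(as.integer(r), collapse = "")), count = as.integer(counts),
    stringsAsFactors = FALSE)
  names(out)[1:3] <- nm
  rownames(out) <- NULL
  out[order(out$region, decreasing = TRUE), , drop = FALSE]
}
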