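# Independent oracle: the published ACMG combining rules written as
# direct boolean logic over strength counts (not via the shipped rule
# table), used to cross-check the table-driven engine.
richardsOracle <- function(codes, strengths = character()) {
  str <- ifelse(grepl("^PVS", codes), "very_strong",
         ifelse(grepl("^PS", codes), "strong",
         ifelse(grepl("^PM", codes), "moderate",
         ifelse(grepl("^PP", codes), "supporting",
         ifelse(grepl("^BA", codes), "stand_alone",
         ifelse(grepl("^BS", codes), "strong", "supporting"))))))
  if (length(strengths)) str[match(names(strengths), codes)] <- strengths
  pat <- !grepl("^B", codes)
  vs <- sum(pat & str == "very_strong"); s <- sum(pat & str == "strong")
  m <- sum(pat & str == "moderate"); p <- sum(pat & str == "supporting")
  ba <- sum(!pat & str == "stand_alone"); bs <- sum(!pat & str == "strong")
  bp <- sum(!pat & str == "supporting")
  pathogenic <- vs >= 2 ||
    (vs == 1 && (s >= 1 || m >= 2 || (m == 1 && p >= 1) || p >= 2)) ||
    s >= 2 ||
    (s == 1 && (m >= 3 || (m == 2 && p >= 2) || (m == 1 && p >= 4)))
  likely_path <- (vs == 1 && m == 1) ||
    (s == 1 && m >= 1 && m <= 2) || (s == 1 && p >= 2) ||
    m >= 3 || (m == 2 && p >= 2) || (m == 1 && p >= 4)
  benign <- ba >= 1 || bs >= 2
  likely_ben <- (bs == 1 && bp >= 1) || bp >= 2
  if ((pathogenic || likely_path) && (benign || likely_ben))
    return("uncertain_significance")
  if (pathogenic) return("pathogenic")
  if (likely_path) return("likely_pathogenic")
  if (benign) return("benign")
  if (likely_ben) return("likely_benign")
  "uncertain_significance"
}
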