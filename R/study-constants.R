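# Published summary tables for the three-species syntopic frog assemblage
# (two Microhyla species and Occidozyga lingnanica).  These printed values
# are the inputs that parameterize the synthetic generator and the
# desk-scale index computations; raw per-stomach data were not deposited.

#' Published dietary composition table (percentages)
#'
#' Per-species, per-prey-category percentages: frequency of occurrence
#' (`pctF`), numeric proportion (`pctN`), volumetric proportion (`pctV`)
#' and the index of relative importance (`IRI`), at the finest identified
#' taxon level (family, larval bin, or residual bin; two taxa are carried
#' at order level because no finer bin was identified).  `NA` marks a
#' taxon absent from that species' diet.
#'
#' @return data frame with columns `prey_order`, `prey_category`, and for
#'   each species suffix (`mukhlesuri`, `heymonsi`, `lingnanica`) the four
#'   percentage columns.
#' @export
study_composition <- function() {
  # prey_order, prey_category, then F/N/V/IRI for mukhlesuri, heymonsi,
  # lingnanica (NA = absent)
  rec <- function(ord, cat, mm, mh, ol) {
    c(list(prey_order = ord, prey_category = cat),
      stats::setNames(as.list(c(mm, mh, ol)),
                      paste0(rep(c("mukhlesuri", "heymonsi", "lingnanica"),
                                 each = 4),
                             "_", rep(c("pctF", "pctN", "pctV", "IRI"), 3))))
  }
  na4 <- rep(NA_real_, 4)
  rows <- list(
    rec("Decapoda", "Atyidae", na4, na4, c(1.75, 1.07, 6.31, 3.04)),
    rec("Isopoda", "Armadillidiidae", na4, na4, c(1.75, 1.07, 5.26, 2.70)),
    rec("Gastropoda", "Gastropoda", na4, na4, c(6.14, 3.21, 2.44, 3.93)),
    rec("Araneae", "Araneae", c(1.14, 0.11, 0.05, 0.43), na4,
        c(3.51, 1.43, 1.34, 2.09)),
    rec("Coleoptera", "Carabidae", na4, c(2.33, 0.20, 0.12, 0.88),
        c(0.88, 0.36, 1.80, 1.01)),
    rec("Coleoptera", "Curculionidae", na4, c(2.33, 0.20, 0.09, 0.87), na4),
    rec("Coleoptera", "Chrysomelidae", c(1.14, 0.11, 0.05, 0.43), na4, na4),
    rec("Coleoptera", "Dytiscidae", na4, na4, c(0.88, 1.07, 0.19, 0.71)),
    rec("Coleoptera", "Hydrophilidae", c(6.82, 1.48, 0.73, 3.01),
        c(2.33, 0.20, 0.09, 0.87), c(6.14, 3.57, 2.42, 4.04)),
    rec("Coleoptera", "Larvae Coleoptera", c(7.95, 1.37, 8.89, 6.07),
        c(6.98, 0.60, 0.20, 2.59), c(12.28, 15.71, 34.04, 20.68)),
    rec("Coleoptera", "Nitidulidae", c(1.14, 0.11, 0.02, 0.42),
        c(2.33, 0.20, 0.03, 0.85), c(5.26, 3.93, 2.31, 3.84)),
    rec("Coleoptera", "Phalacridae", c(5.68, 0.80, 1.10, 2.52),
        c(2.33, 0.20, 0.99, 1.17), c(3.51, 1.43, 0.27, 1.73)),
    rec("Coleoptera", "Staphylinidae", na4, na4, c(4.39, 2.86, 0.69, 2.64)),
    rec("Coleoptera", "Tenebrionidae", na4, na4, c(0.88, 0.71, 0.37, 0.66)),
    rec("Coleoptera", "Other Coleoptera", c(1.14, 0.11, 0.07, 0.44), na4,
        c(14.04, 13.93, 7.69, 11.89)),
    rec("Diptera", "Larvae Diptera", na4, na4, c(1.75, 2.14, 4.18, 2.69)),
    rec("Diptera", "Drosophilidae", na4, na4, c(1.75, 1.07, 0.13, 0.99)),
    rec("Diptera", "Culicoidea", na4, na4, c(0.88, 0.36, 0.01, 0.41)),
    rec("Hemiptera", "Cicadellidae", na4, na4, c(0.88, 0.36, 0.64, 0.63)),
    rec("Hemiptera", "Gerridae", na4, na4, c(0.88, 1.43, 0.29, 0.87)),
    rec("Hemiptera", "Pentatomidae", na4, na4, c(1.75, 1.07, 0.86, 1.23)),
    rec("Hemiptera", "Mesoveliidae", c(1.14, 0.11, 0.11, 0.45), na4,
        c(2.63, 1.43, 0.19, 1.42)),
    rec("Hymenoptera", "Apidae", na4, na4, c(0.88, 0.36, 8.02, 3.08)),
    rec("Hymenoptera", "Formicidae", c(31.82, 19.82, 10.32, 20.65),
        c(25.58, 6.19, 3.52, 11.76), c(7.02, 6.43, 2.70, 5.38)),
    rec("Isoptera", "Termitidae", c(40.91, 75.85, 78.63, 65.13),
        c(55.81, 92.22, 94.94, 80.99), c(7.89, 14.64, 1.76, 8.10)),
    rec("Lepidoptera", "Larvae Lepidoptera", na4, na4,
        c(0.88, 0.36, 0.86, 0.70)),
    rec("Orthoptera", "Acrididae", na4, na4, c(6.14, 13.57, 5.74, 8.48)),
    rec("Orthoptera", "Gryllidae", na4, na4, c(3.51, 5.00, 2.52, 3.68)),
    rec("Thysanoptera", "Thripidae", c(1.14, 0.11, 0.03, 0.43), na4,
        c(0.88, 0.36, 0.13, 0.46)),
    rec("Gobiiformes", "Gobiidae", na4, na4, c(0.88, 1.07, 6.84, 2.93)))
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Published per-species stomach and prey-size summary
#'
#' Mean, SD and printed range of the per-stomach item count (`N`), prey
#' width (`W`, mm), length (`L`, mm) and total stomach-content volume
#' (`V`, mm^3), plus stomach and item totals.
#'
#' @return data frame with one row per species x variable.
#' @export
study_prey_summary <- function() {
  out <- data.frame(
    species = rep(c("Microhyla heymonsi", "Microhyla mukhlesuri",
                    "Occidozyga lingnanica"), each = 4),
    n_stomachs = rep(c(26L, 42L, 48L), each = 4),
    n_items = rep(c(501L, 878L, 280L), each = 4),
    variable = rep(c("N", "W", "L", "V"), 3),
    mean = c(19.27, 1.09, 2.51, 32.42,
             20.90, 0.96, 2.03, 22.86,
             5.83, 1.35, 3.66, 40.80),
    sd = c(15.57, 0.19, 1.28, 34.57,
           22.58, 0.21, 1.17, 32.52,
           4.42, 0.72, 3.14, 50.53),
    min = c(1, 0.5, 0.5, 0.92,
            3, 0.5, 0.5, 1.11,
            1, 0.5, 0.5, 1.05),
    max = c(60, 2.0, 5.0, 121.41,
            125, 3.0, 12.0, 143.66,
            19, 5.0, 20.0, 266.59),
    stringsAsFactors = FALSE)
  out
}

#' Published morphometric summary and pairwise Pearson correlations
#'
#' Sex-pooled means/SDs and printed ranges of snout-vent length (SVL),
#' head length (HL), mouth width (MW) and body mass (BM), with the
#' published pairwise Pearson correlations among SVL, MW and BM and the
#' per-species counts of males and females.
#'
#' @return list with elements `moments` (data frame) and `correlations`
#'   (data frame with `r_svl_mw`, `r_svl_bm`, `r_mw_bm`, `n_male`,
#'   `n_female`).
#' @export
study_morphometrics <- function() {
  moments <- data.frame(
    species = rep(c("Microhyla mukhlesuri", "Microhyla heymonsi",
                    "Occidozyga lingnanica"), each = 4),
    variable = rep(c("svl_mm", "hl_mm", "mw_mm", "bm_g"), 3),
    mean = c(22.10, 6.80, 5.64, 1.32,
             23.45, 6.96, 5.99, 1.87,
             24.91, 8.70, 7.61, 1.96),
    sd = c(3.20, 0.86, 0.74, 0.56,
           2.54, 0.74, 0.54, 0.70,
           3.70, 1.05, 1.00, 0.96),
    min = c(16.2, 5.0, 4.0, 0.55,
            19.1, 5.3, 4.9, 0.72,
            19.0, 6.4, 5.8, 0.75),
    max = c(28.9, 9.0, 7.5, 3.10,
            27.4, 8.1, 6.7, 3.02,
            32.5, 10.6, 9.5, 4.36),
    stringsAsFactors = FALSE)
  correlations <- data.frame(
    species = c("Microhyla mukhlesuri", "Microhyla heymonsi",
                "Occidozyga lingnanica"),
    r_svl_mw = c(0.905, 0.839, 0.924),
    r_svl_bm = c(0.943, 0.945, 0.950),
    r_mw_bm = c(0.897, 0.827, 0.886),
    n_male = c(31L, 6L, 33L),
    n_female = c(11L, 20L, 15L),
    stringsAsFactors = FALSE)
  list(moments = moments, correlations = correlations)
}
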