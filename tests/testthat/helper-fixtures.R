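# In-code fixtures: tiny hand-built datasets used across test files.

diet_row <- function(sample_id, species = "sp1", sex = "male",
                     svl = 20, hl = 6, mw = 5, bm = 1,
                     order = "Isoptera", category = "Termitidae",
                     len = 2, wid = 1) {
  data.frame(sample_id = sample_id, species = species, sex = sex,
             svl_mm = svl, hl_mm = hl, mw_mm = mw, bm_g = bm,
             microhabitat = NA_character_,
             prey_order = order, prey_category = category,
             prey_length_mm = len, prey_width_mm = wid,
             stringsAsFactors = FALSE)
}

empty_stomach_row <- function(sample_id, species = "sp1", ...) {
  diet_row(sample_id, species, order = NA_character_,
           category = NA_character_, len = NA_real_, wid = NA_real_, ...)
}

# two stomachs, three items, two taxa
tiny_diet <- function() {
  diet_dataset(rbind(
    diet_row("a", category = "Termitidae", order = "Isoptera"),
    diet_row("a", category = "Formicidae", order = "Hymenoptera"),
    diet_row("b", category = "Termitidae", order = "Isoptera",
             len = 4, wid = 2)))
}

# published category-level numeric proportions (%N) per species
study_pctN <- function(key) {
  comp <- study_composition()
  v <- comp[[paste0(key, "_pctN")]]
  keep <- !is.na(v) & v > 0
  stats::setNames(v[keep], comp$prey_category[keep])
}
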