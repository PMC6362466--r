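# Hand-built case rows for unit tests.

make_case <- function(case_id = "c1", age_years = 55L, stage = "I",
                      tumor_size_cm = 1.5, nodes_positive = 0L, grade = "II",
                      her2 = "neg", hr = "pos", histology_icdo3 = 8500L,
                      behavior = "invasive", fascia = FALSE, skin = FALSE,
                      mets = FALSE, surgery_class = "bcs", region = "iowa",
                      race = "white") {
  data.frame(
    case_id = case_id, age_years = as.integer(age_years), stage = stage,
    tumor_size_cm = tumor_size_cm, nodes_positive = as.integer(nodes_positive),
    grade = grade, her2 = her2, hr = hr,
    histology_icdo3 = as.integer(histology_icdo3), behavior = behavior,
    invades_fascia_muscle_chestwall = fascia,
    skin_ulceration_or_adjacent_skin = skin, distant_metastasis = mets,
    surgery_class = surgery_class, region = region, race = race,
    stringsAsFactors = FALSE
  )
}

make_cohort <- function(...) {
  rows <- list(...)
  cases <- do.call(rbind, rows)
  cases$case_id <- sprintf("c%03d", seq_len(nrow(cases)))
  new_cohort(cases)
}
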