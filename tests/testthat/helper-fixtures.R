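# small hand-built cohort: two persons, three nights for p1, none for p2
make_tiny_cohort <- function() {
  persons <- tibble::tibble(
    person_id = c("p1", "p2"),
    age = c(15, 17), sex = c(1, 0),
    maternal_education = c(14, 16), income_to_needs = c(2.1, 3.4)
  )
  for (f in facet_names) {
    persons[[paste0(f, "_cg")]] <- c(52, 47)
    persons[[paste0(f, "_yr")]] <- c(55, 45)
  }
  nights <- tibble::tibble(
    person_id = "p1", night_index = 0:2, weekend = c(0, 0, 1),
    duration_min = c(400, 380, 420),
    bedtime_min = c(-30, 10, 45), waketime_min = c(430, 440, 500)
  )
  cohort(persons, nights)
}

# a quick mid-sized generated cohort shared across tests
small_cohort <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      cfg <- default_paper_config(n_persons = 150L, seed = 404L)
      val <<- generate_cohort(cfg)
    }
    val
  }
})
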