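# Canonical symptom instrument schema: 37 presence/absence items arranged in
# 10 individual domains, two global domains (psychological = depression +
# anxiety; physical = the remaining eight), and an overall summary.
# Ingestion matches on these identifiers, never on free text.

.SYMPTOM_ITEMS <- list(
  depression = c(
    "thoughts_of_ending_life", "feeling_lonely", "feeling_blue",
    "feeling_no_interest", "feeling_hopeless", "feelings_of_worthlessness"
  ),
  anxiety = c(
    "nervousness_shaking", "suddenly_scared", "feeling_fearful",
    "feeling_tense", "spells_of_terror_panic", "restless_cannot_sit_still"
  ),
  sensory = c(
    "decreased_sense_of_touch", "tinnitus", "dizziness", "double_vision",
    "other_trouble_seeing", "very_dry_eyes", "abnormal_sense_of_taste",
    "numbness"
  ),
  motor = c(
    "problem_with_balance", "tremors_movement_problems",
    "weakness_arm", "weakness_leg"
  ),
  cardiac = c("arrhythmia", "angina_pectoris", "chest_pain_with_exercise"),
  respiratory = c("chronic_cough", "trouble_getting_breath"),
  memory = "problems_learning_memory",
  pain = c(
    "migraine", "pain_in_heart_chest", "severe_headache",
    "prolonged_pain_arms_legs_back"
  ),
  gastrointestinal = "nausea_upset_stomach",
  fatigue = c("faintness", "feeling_weak")
)

.PSYCHOLOGICAL_DOMAINS <- c("depression", "anxiety")

.WAVES <- c("T1", "T2", "T3")

.PATTERNS <- paste0("P", 1:10)

.PATTERN_LABELS <- c(
  P1 = "Early Escalation", P2 = "Late Escalation",
  P3 = "Early Resolution", P4 = "Late Resolution",
  P5 = "Persistent Presence", P6 = "Early Limited Persistence",
  P7 = "Late Limited Persistence", P8 = "Consistent Absence",
  P9 = "Early Limited Absence", P10 = "Late Limited Absence"
)

#' Canonical symptom items and their domain assignment
#'
#' The symptom instrument has 37 presence/absence items grouped into 10
#' individual domains (depression, anxiety, sensory, motor, cardiac,
#' respiratory, memory, pain, gastrointestinal, fatigue). Depression and
#' anxiety form the psychological global domain (12 items); the remaining
#' eight domains form the physical global domain (25 items).
#'
#' @return A data frame with one row per item and columns `item`, `domain`,
#'   and `global_domain` (`"psychological"` or `"physical"`), in canonical
#'   item order.
#' @export
#' @examples
#' nrow(symptom_items())  # 37
#' table(symptom_items()$global_domain)
symptom_items <- function() {
  items <- unlist(.SYMPTOM_ITEMS, use.names = FALSE)
  domain <- rep(names(.SYMPTOM_ITEMS), lengths(.SYMPTOM_ITEMS))
  data.frame(
    item = items,
    domain = domain,
    global_domain = ifelse(domain %in% .PSYCHOLOGICAL_DOMAINS,
                           "psychological", "physical"),
    stringsAsFactors = FALSE
  )
}

#' Aggregated cross-sectional symptom summaries
#'
#' Eleven count summaries are defined on top of the 37 items: the eight
#' multi-item individual domains (memory and gastrointestinal are excluded
#' from summarisation because each holds a single item, though their items
#' still contribute to the global and overall counts), the two global
#' domains, and the overall count of all 37 items.
#'
#' @return A data frame with columns `measure`, `kind` (always `"summary"`),
#'   `n_members`, and a list-column `members` of member item names.
#' @export
summary_measures <- function() {
  si <- symptom_items()
  multi <- names(.SYMPTOM_ITEMS)[lengths(.SYMPTOM_ITEMS) > 1L]
  members <- c(
    lapply(multi, function(d) si$item[si$domain == d]),
    list(si$item[si$global_domain == "psychological"]),
    list(si$item[si$global_domain == "physical"]),
    list(si$item)
  )
  measure <- c(paste0(multi, "_summary"),
               "psychological_summary", "physical_summary", "overall_summary")
  out <- data.frame(
    measure = measure,
    kind = "summary",
    n_members = lengths(members),
    stringsAsFactors = FALSE
  )
  out$members <- members
  out
}

#' All 48 cross-sectional symptom measures
#'
#' The 37 item indicators plus the 11 aggregated summaries, i.e. the 48
#' cross-sectional symptom measures available at each survey wave.
#'
#' @return A data frame with columns `measure`, `kind` (`"item"` or
#'   `"summary"`), `n_members`, and list-column `members`.
#' @export
measure_schema <- function() {
  si <- symptom_items()
  item_part <- data.frame(
    measure = si$item, kind = "item", n_members = 1L,
    stringsAsFactors = FALSE
  )
  item_part$members <- as.list(si$item)
  rbind(item_part, summary_measures())
}

#' Non-symptom covariate schema
#'
#' The 35 non-symptom predictors: 8 demographic variables (five continuous
#' ages/intervals in years; sex, race/ethnicity and educational attainment as
#' binary indicators), 8 cancer diagnosis indicators (seven named diagnoses
#' plus other malignancy, no reference category dropped), and 19 treatment
#' exposure indicators (12 chemotherapy agents, 5 radiation sites,
#' amputation, other surgery).
#'
#' @return A data frame with columns `name`, `type` (`"continuous"` or
#'   `"binary"`), and `category` (`"demographic"`, `"diagnosis"`,
#'   `"treatment"`).
#' @export
#' @examples
#' nrow(covariate_schema())  # 35
covariate_schema <- function() {
  demo <- data.frame(
    name = c("age_t1", "time_t1_hrqol", "age_t3", "time_t3_hrqol",
             "age_diagnosis", "sex_female", "race_white", "educ_college"),
    type = c(rep("continuous", 5L), rep("binary", 3L)),
    category = "demographic", stringsAsFactors = FALSE
  )
  dx <- data.frame(
    name = c("dx_leukemia", "dx_hodgkin", "dx_non_hodgkin", "dx_osteosarcoma",
             "dx_wilms", "dx_cns", "dx_neuroblastoma", "dx_other"),
    type = "binary", category = "diagnosis", stringsAsFactors = FALSE
  )
  tx <- data.frame(
    name = c("chemo_methotrexate", "chemo_it_methotrexate",
             "chemo_hd_methotrexate", "chemo_cytarabine",
             "chemo_it_cytarabine", "chemo_hd_cytarabine", "chemo_bleomycin",
             "chemo_alkylating", "chemo_anthracycline", "chemo_corticosteroid",
             "chemo_plant_alkaloid", "chemo_platinum",
             "rt_brain", "rt_neck", "rt_chest", "rt_abdomen", "rt_pelvis",
             "surgery_amputation", "surgery_other"),
    type = "binary", category = "treatment", stringsAsFactors = FALSE
  )
  rbind(demo, dx, tx)
}

#' Longitudinal symptom change patterns
#'
#' The ten trajectory codes applied to every cross-sectional measure:
#' P1 early escalation (absent T1, present T2); P2 late escalation (absent
#' T2, present T3); P3 early resolution (present T1, absent T2); P4 late
#' resolution (present T2, absent T3); P5 persistent presence (+,+,+);
#' P6 early limited persistence (+,+,-); P7 late limited persistence
#' (-,+,+); P8 consistent absence (-,-,-); P9 early limited absence (-,-,+);
#' P10 late limited absence (+,-,-).
#'
#' @return Named character vector of pattern labels, names `P1`..`P10`.
#' @export
pattern_labels <- function() .PATTERN_LABELS
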