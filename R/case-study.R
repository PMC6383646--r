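#' Peripartum anxiety case-study dataset
#'
#' The embedded case study: 20 samples from 18 articles (10,033 pregnant or
#' postpartum participants) reporting the prevalence of at least one of six
#' anxiety and related disorders -- panic disorder, obsessive-compulsive
#' disorder (OCD), generalized anxiety disorder (GAD), social phobia,
#' specific phobia, and posttraumatic stress disorder (PTSD).
#'
#' Published per-disorder percentages are converted to integer counts by
#' rounding `prevalence% * N / 100` to the nearest integer; reported 0.0%
#' cells become counts of zero (legal binomial data -- any continuity
#' correction is an estimator concern, not a data concern). The two
#' pregnant/postpartum sample pairs drawn from a single parent study (Mota
#' 2008 and Fisher 2010a) share a `cluster_id` so that model fits estimate a
#' single "true" prevalence for each parent study. Seven samples contributed
#' individual participant data to the original analysis; they are flagged via
#' `ipd_available`, but the raw IPD are not distributed and are not
#' fabricated -- the fixture carries aggregate data only.
#'
#' @return A [meta_dataset()] with 20 samples, 18 clusters and an empty `ipd`
#'   list.
#' @examples
#' d <- case_study_table1()
#' sum(d$samples$N)                        # 10033 participants
#' sum(d$samples$N[d$samples$ipd_available])  # 1506 with IPD available
#' @export
case_study_table1 <- function() {
  panel <- disorder_panel(c("panic", "ocd", "gad", "social_phobia",
                            "specific_phobia", "ptsd"))
  txt <- "sample_id,cluster_id,N,any,panic,ocd,gad,social_phobia,specific_phobia,ptsd,ipd
Zar_2002,Zar_2002,453,21.9,1.3,0.2,0.9,2.7,18.3,1.3,1
Wenzel_2004,Wenzel_2004,68,4.4,,,4.4,,,,0
Wenzel_2005,Wenzel_2005,147,,1.4,2.7,8.2,4.1,,,0
Uguz_2007,Uguz_2007,434,3.5,,3.5,,,,,0
Rogal_2007,Rogal_2007,1100,3.0,,,,,,3.0,0
Mota_2008_preg,Mota_2008,451,13.2,2.1,,1.9,3.3,9.3,,0
Mota_2008_post,Mota_2008,1061,15.0,4.0,,2.3,2.5,10.2,,0
Seng_2010,Seng_2010,1581,7.9,,,,,,7.9,0
Kersting_2009,Kersting_2009,65,0.0,0.0,0.0,,,0.0,0.0,0
Fisher_2010a_preg,Fisher_2010a,199,,1.5,,10.6,,,,0
Fisher_2010a_post,Fisher_2010a,165,,4.2,,11.5,,,,0
Chaudron_2010,Chaudron_2010,24,37.5,4.2,29.2,,,8.3,8.3,1
Fisher_2010b,Fisher_2010b,196,8.7,0.0,,2.6,3.6,3.6,,1
Uguz_2010,Uguz_2010,309,15.5,1.9,5.2,3.6,3.2,3.2,0.0,0
Matthey_2011,Matthey_2011,171,14.0,2.9,2.9,11.1,4.1,,0.6,1
Prenoveau_2013,Prenoveau_2013,2202,5.5,,,5.5,,,,0
Fadzil_2013,Fadzil_2013,175,6.3,5.7,0.0,0.0,0.6,,0.0,1
Kim_2015,Kim_2015,745,6.6,,,,,,6.6,0
Usuda_2016,Usuda_2016,177,3.4,1.1,1.7,0.0,1.1,,0.6,1
Fairbrother_2016,Fairbrother_2016,310,15.2,0.7,3.6,3.2,5.2,7.4,0.7,1"
  raw <- read.csv(text = txt, stringsAsFactors = FALSE)
  to_count <- function(pct, N) ifelse(is.na(pct), NA_integer_,
                                      as.integer(round(pct * N / 100)))
  samples <- data.frame(sample_id = raw$sample_id,
                        cluster_id = raw$cluster_id,
                        N = as.integer(raw$N),
                        any_count = to_count(raw$any, raw$N),
                        stringsAsFactors = FALSE)
  for (d in unclass(panel)) samples[[d]] <- to_count(raw[[d]], raw$N)
  samples$ipd_available <- raw$ipd == 1
  meta_dataset(samples, panel)
}
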