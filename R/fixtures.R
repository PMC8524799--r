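#' Benchmark medical records of 60 patients
#'
#' The 60-patient demonstration dataset used throughout the package: one
#' numerical quasi-identifier (Age), four categorical quasi-identifiers
#' (Gender, Marriage, Smoke, Zip) and the sensitive Diagnosis column.
#' Three rows (1, 23, 46) share zip code 33613; one source rendering of the
#' first row prints 63613, an apparent typo this fixture resolves to 33613
#' to match its duplicates. The Diagnosis column is never part of the
#' clustering schema (see [table3_schema()]).
#'
#' @return A 60-row data frame with columns `id`, `Gender`, `Age`, `Zip`,
#'   `Marriage`, `Smoke`, `Diagnosis` (`Age` numeric, all else character).
#' @export
table3_records <- function() {
  txt <- "id,Gender,Age,Zip,Marriage,Smoke,Diagnosis
1,F,56,33613,Divorce,Y,AA
2,F,60,33647,Marriage,N,Diabetes
3,M,81,34660,Single,N,AA
4,M,44,32801,Divorce,Y,AA
5,M,56,32211,Marriage,N,AA
6,M,34,32868,Marriage,N,Normal
7,F,73,34768,Single,N,AA
8,M,77,33102,Marriage,N,AA
9,F,84,32855,Single,N,AA
10,F,68,33709,Marriage,N,ACML
11,F,66,34302,Marriage,Y,Diabetes
12,M,53,34565,Single,Y,AML
13,M,59,32652,Marriage,Y,AITCL
14,F,63,33615,Marriage,N,Normal
15,F,19,75865,Single,N,AML
16,M,38,33650,Single,Y,Normal
17,M,56,75677,Marriage,N,Normal
18,F,67,33218,Marriage,N,AA
19,M,65,34813,Marriage,N,ACML
20,M,71,32556,Marriage,N,Normal
21,F,67,33451,Marriage,Y,AML FROM MDS
22,M,60,33648,Marriage,Y,Normal
23,F,56,33613,Divorce,N,AA
24,F,60,33647,Marriage,Y,AA
25,M,51,34660,Single,N,ACML
26,M,34,32801,Divorce,N,Normal
27,M,56,32211,Marriage,N,AML FROM MDS
28,M,34,32868,Marriage,Y,ACML
29,M,38,72868,Marriage,N,ACML
30,F,73,34768,Single,N,AA
31,F,57,33102,Marriage,N,AA
32,F,84,32855,Single,N,AA
33,F,60,33709,Marriage,N,Diabetes
34,F,66,34302,Marriage,Y,ACML
35,M,73,34565,Single,N,AML
36,M,59,32652,Marriage,N,AITCL
37,F,43,33615,Marriage,Y,AML
38,F,29,75865,Single,Y,AML
39,M,48,33650,Single,N,AML
40,M,76,75677,Marriage,N,Normal
41,F,37,33218,Marriage,Y,AML
42,M,45,34813,Marriage,N,AML
43,M,51,32556,Marriage,N,AITCL
44,F,67,33451,Marriage,N,AML
45,M,60,33648,Marriage,N,Normal
46,F,56,33613,Divorce,Y,AA
47,F,63,33647,Marriage,N,AA
48,M,56,34660,Marriage,N,Normal
49,M,34,32801,Divorce,Y,AML
50,M,52,32211,Marriage,N,AITCL
51,M,34,32868,Marriage,N,Normal
52,F,43,34768,Single,Y,AA
53,M,38,75685,Marriage,Y,AML FROM MDS
54,M,42,72512,Marriage,Y,ACML
55,M,26,75828,Single,Y,ACML
56,F,33,34574,Single,N,AA
57,M,47,34543,Marriage,Y,ACML
58,F,62,32767,Marriage,Y,Normal
59,M,55,75926,Marriage,Y,AML
60,M,42,75384,Marriage,Y,AML"
  df <- utils::read.csv(text = txt, colClasses = "character",
                        check.names = FALSE)
  df$Age <- as.numeric(df$Age)
  df
}

#' Default schema for the 60-patient dataset
#'
#' Age is the single numerical attribute. The categorical hierarchies are
#' the package defaults: Gender and Smoke are flat two-leaf trees
#' (height 1), Marriage a flat three-leaf tree over
#' Single/Marriage/Divorce (height 1), and Zip the three-level prefix tree
#' full code -> 3-digit prefix -> root (height 2), built from the zip codes
#' observed in [table3_records()]. All are overridable via the JSON
#' hierarchy format when calling [read_inputs()].
#'
#' @return An [attribute_schema()].
#' @export
table3_schema <- function() {
  recs <- table3_records()
  attribute_schema(
    numerical = "Age",
    categorical = list(
      Gender = flat_hierarchy(c("M", "F"), root = "gender:*"),
      Marriage = flat_hierarchy(c("Single", "Marriage", "Divorce"),
                                root = "marriage:*"),
      Smoke = flat_hierarchy(c("Y", "N"), root = "smoke:*"),
      Zip = zip_prefix_hierarchy(recs$Zip)
    )
  )
}

#' The linkage-attack demonstration tables
#'
#' A seven-row private hospital table (zip code, age, disease) and a
#' six-row public table (name, gender, zip code, age) illustrating
#' re-identification by joining on the quasi-identifiers. Zip codes are
#' six-digit strings; ages are two-digit integers.
#'
#' @return List with data frames `private` (columns `ID`, `Zip`, `Age`,
#'   `Disease`) and `public` (columns `ID`, `Name`, `Gender`, `Zip`,
#'   `Age`); `Age` numeric, zips character.
#' @export
link_attack_tables <- function() {
  private <- utils::read.csv(text = "ID,Zip,Age,Disease
1,273212,33,heart disease
2,273215,45,heart disease
3,273203,23,influenza
4,273211,29,heart disease
5,273207,50,cancer
6,273206,20,influenza
7,273221,31,A-dis", colClasses = "character", check.names = FALSE)
  private$Age <- as.numeric(private$Age)
  public <- utils::read.csv(text = "ID,Name,Gender,Zip,Age
1,Mary,Male,273209,29
2,Alice,Female,273212,33
3,David,Male,273211,29
4,Sam,Female,273207,50
5,Joan,Male,273206,20
6,Angle,Female,273221,31", colClasses = "character", check.names = FALSE)
  public$Age <- as.numeric(public$Age)
  list(private = private, public = public)
}

#' Reference loss grids of the 60-patient benchmark
#'
#' The generalization-loss and structure-loss values reported for the
#' benchmark network over the parameter grid k = 3, 6, ..., 30 and
#' a = 0, 0.2, ..., 1, embedded verbatim. The edge list behind these
#' numbers was never published, so they serve as reference points (e.g.
#' their cell-wise sum is minimized at k = 3, a = 1 at 0.302819), not as
#' reproduction targets for [sweep_losses()] on synthetic edges.
#'
#' @return List of two 10 x 6 numeric matrices, `generalization` and
#'   `structure`, with k values as row names and a values as column names.
#' @export
printed_loss_grids <- function() {
  k <- c(3, 6, 9, 12, 15, 18, 21, 24, 27, 30)
  a <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  gen <- matrix(c(
    0.278462, 0.240051, 0.240051, 0.240051, 0.240051, 0.118513,
    0.242615, 0.222410, 0.222410, 0.222410, 0.224000, 0.140103,
    0.211692, 0.216103, 0.216103, 0.216103, 0.213051, 0.127205,
    0.211026, 0.213744, 0.209615, 0.195641, 0.190718, 0.124282,
    0.202949, 0.215513, 0.215513, 0.204872, 0.207949, 0.135513,
    0.214872, 0.214872, 0.214872, 0.214872, 0.198615, 0.123538,
    0.200333, 0.200333, 0.200333, 0.200333, 0.196923, 0.116333,
    0.203256, 0.203256, 0.203256, 0.203256, 0.192000, 0.121400,
    0.201795, 0.201795, 0.201795, 0.201795, 0.202949, 0.134615,
    0.206667, 0.206667, 0.206667, 0.206667, 0.197308, 0.152821
  ), nrow = 10, byrow = TRUE, dimnames = list(k, a))
  str <- matrix(c(
    0.156685, 0.150157, 0.150157, 0.150157, 0.150157, 0.184306,
    0.182498, 0.182172, 0.182172, 0.182172, 0.182097, 0.205461,
    0.184150, 0.188338, 0.188338, 0.188338, 0.188031, 0.208391,
    0.192364, 0.192580, 0.192517, 0.195209, 0.196268, 0.209272,
    0.195478, 0.195952, 0.195952, 0.197481, 0.195349, 0.210337,
    0.198426, 0.198426, 0.198426, 0.198426, 0.198616, 0.210719,
    0.200807, 0.200807, 0.200807, 0.200807, 0.201999, 0.210436,
    0.204509, 0.204509, 0.204509, 0.204509, 0.201373, 0.210497,
    0.204427, 0.204427, 0.204427, 0.204427, 0.204442, 0.211029,
    0.205762, 0.205762, 0.205762, 0.205762, 0.207728, 0.211137
  ), nrow = 10, byrow = TRUE, dimnames = list(k, a))
  list(generalization = gen, structure = str)
}
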