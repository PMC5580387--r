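# Profile builders and the frozen 12-row regression matrix used across
# test files (feature letters per state column, as published).

mkprofile <- function(C = "", X = "", T = "") {
  split1 <- function(s) if (nzchar(s)) strsplit(s, ",")[[1]] else character(0)
  p <- list()
  for (ch in split1(C)) p[[ch]] <- "C"
  for (ch in split1(X)) p[[ch]] <- "X"
  for (ch in split1(T)) p[[ch]] <- "T"
  character_profile(.states = p)
}

all_c_profile <- function() {
  mkprofile(C = paste(letters[1:12], collapse = ","))
}

# specimen id -> feature letters by state, plus the published identity call
table4_rows <- list(
  "RGM 139671" = list(C = "f,h", X = "", T = "a,b,c,d,e,g,i,j,k,l", id = "T1"),
  "RGM 146833" = list(C = "b,d,e", X = "f,j,k,l", T = "a,g", id = "CT"),
  "RGM 171525" = list(C = "a,b,e,g,h,i,j,k,l", X = "d,f", T = "", id = "C7"),
  "RGM 369367" = list(C = "a,b,c,d,e,g,h,i,j,k,l", X = "f", T = "", id = "C7"),
  "RGM 369657" = list(C = "a,b,e,f,g,h,i,j,k,l", X = "d", T = "", id = "C7"),
  "RGM 445933" = list(C = "b,d,e,g,j", X = "f,l", T = "a,k", id = "CT"),
  "RGM 55336" = list(C = "", X = "f", T = "a,b,c,d,e,g,j,k,l", id = "T1"),
  "RGM 93477" = list(C = "c,g", X = "a,e,f,j", T = "b,d,k,l", id = "CT"),
  "RGM 93479" = list(C = "f", X = "", T = "a,b,c,d,e,g,h,i,j,k,l", id = "T1"),
  "RGM 93485" = list(C = "e", X = "", T = "a,d,f,g,j,k,l", id = "T1"),
  "RGM 93790" = list(C = "e", X = "a,c,d,f,j,k,l", T = "b,g", id = "CT"),
  "RGM 94549" = list(C = "c,e,f,g,h,i", X = "b,d,j,l", T = "a,k", id = "CT")
)

table4_record <- function(id) {
  d <- table4_rows[[id]]
  vertebra_record(id, taxon = "Coelodonta antiquitatis",
                  profile = mkprofile(d$C, d$X, d$T))
}

# random complete profile over all 12 characters
random_profile <- function() {
  character_profile(.states = stats::setNames(
    as.list(sample(c("C", "X", "T"), 12, replace = TRUE)), letters[1:12]))
}

record_with <- function(profile, id = "test") {
  vertebra_record(id, profile = profile)
}

# deterministic per-replicate seeds for coverage-style loops
derive_seed_for_test <- function(i) (101L + 7919L * i) %% 2147483647L
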