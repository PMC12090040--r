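#!/usr/bin/env Rscript
# Stage 2 -- drought indices from the monthly climate: Thornthwaite PET,
# SPEI at 3/6/12-month scales, hydrological-year precipitation, and the
# 6 driest / 6 wettest / 6 average years from August SPEI12.

library(dendrotraits)

climate <- read_climate_csv("results/data/climate_monthly.csv", latitude = 40.5)

for (k in c(3, 6, 12)) {
  s <- spei(climate, k, 40.5)
  write_output_csv(s, sprintf("results/spei%02d.csv", k))
}
s12 <- read.csv("results/spei12.csv")
aug <- s12[s12$month == 8 & s12$year %in% 1978:2016, c("year", "spei")]

hp <- hydro_year_precip(climate)
write_output_csv(hp, "results/hydro_year_precip.csv")

classes <- classify_extreme_years(s12[s12$year %in% 1978:2016, ], n = 6)
write_output_csv(data.frame(class = rep(names(classes), lengths(classes)),
                            year = unlist(classes, use.names = FALSE)),
                 "results/extreme_years.csv")

dry <- aug[aug$year %in% classes$dry, ]
message("Six driest years (August SPEI12): ",
        paste(dry$year, collapse = ", "), "; all at or below ",
        round(max(dry$spei), 2), ".")
message("Mean hydrological-year precipitation: ",
        round(mean(hp$precip)), " mm; driest-year mean: ",
        round(mean(hp$precip[hp$year %in% classes$dry])), " mm.")
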