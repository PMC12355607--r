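Package: oasisaq
Title: Air Quality Assessment and Grey Forecasting for Arid-Region Cities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for regulatory ambient air quality assessment in
    arid-region (oasis) cities: aggregation of hourly station data to
    daily, monthly and annual statistics; individual and daily Air
    Quality Index (IAQI/AQI) computation from piecewise-linear
    breakpoint tables with level classification and compliance tallies;
    screening of dust-storm-affected days by the PM2.5/PM10 ratio rule
    with deduction accounting of the dust contribution to annual PM10
    and to the comprehensive pollution index; sum-of-ratio comprehensive
    index and year-on-year comparison tables; Spearman rank trend
    testing against critical values; Pearson correlation matrices and
    heating/non-heating period splits; grey relational analysis of
    socio-economic drivers; and GM(1,1) grey forecasting with
    posterior-variance accuracy grading. A seeded synthetic-data
    generator emulates the seasonal, dust-event and correlation
    structure of arid-city monitoring records so that every stage is
    testable without access to a monitoring archive.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
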