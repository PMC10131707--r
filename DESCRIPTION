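Package: telerota
Title: Staff Rostering for Hub-and-Spoke Telehealth Services
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision support for staffing a hub-and-spoke telehealth
    service such as a child and adolescent mental health (CAMHS) liaison
    team. Forecasts location- and weekday-dependent patient demand from
    historical counts with a calendar-covariate regression, derives
    contract-compliant staff availability calendars, and solves a binary
    integer program that assigns each practitioner, each day, to a
    hospital site, the telehealth hub, or a day off. The program either
    minimizes the number of staff-day assignments needed to cover demand,
    minimizes the total round-trip miles travelled, or optimizes both
    lexicographically. Solutions are rendered as rota and mileage tables,
    and an exhaustive-enumeration oracle is included for verifying the
    exact solver on small instances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    clue,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
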