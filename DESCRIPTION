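Package: footstress
Title: Seated Acute-Stress Detection from Plantar Pressure and Ankle Motion
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects acute stress during seated work from a pressure-sensing
    insole (16 force-sensitive resistors) and an ankle-worn accelerometer.
    Computes ten per-window features over non-overlapping 10 s windows --
    forefoot, rearfoot and total plantar pressure, the two-dimensional centre
    of pressure with rearfoot weighting, per-axis accelerometer means, and
    dominant/median frequency of an axis-inverted 3D acceleration norm --
    and trains linear discriminant models evaluated with leave-one-user-out
    cross-validation. A field mode segments wrist accelerometry into
    walking/standing/sitting postures by acceleration vector change (AVC)
    thresholds, gates foot data to sitting time, and summarises each hour by
    the fraction of sitting windows classified as stressed, correlated
    against hourly self-reported stress. A fully seeded synthetic-data
    generator plants the four seated stress signatures (forefoot loading,
    anterior centre-of-pressure shift, leg-posture change, foot tapping) so
    the whole pipeline is testable without human-subject recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
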