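# Body-segment inertial table for the distributed standing load.
# Columns:
#   label       segment (head HD, cervical C1-C7, thoracic T1-T12, lumbar L1-L5)
#   bm_percent  percent of total body mass (authoritative for mass scaling)
#   mass_printed  historically published per-segment mass (kg) kept for
#                 provenance only; the L4/L5 entries contradict bm_percent at
#                 70.8 kg and are NOT used anywhere in the package
#   iz          local sagittal mass moment of inertia (kg cm^2); the L3 entry
#               refers to a larger (L1-S1) model and is not the local L3/L4
#               term of the effective-inertia sum
#   iz_L3       parallel-axis-transferred inertia about the vertical axis
#               through the L3/L4 center of mass (kg cm^2); T1..L2 only
#   r_mm        anteroposterior eccentricity of the segmental center of mass
#               anterior to the vertebral center (mm). CALIBRATED DEFAULT:
#               the profile shape is anthropometrically plausible and its
#               overall scale is set once so that the mass-weighted mean over
#               HD..L3 equals 41.4 mm.
label,bm_percent,mass_printed,iz,iz_L3,r_mm
HD,4.7,3.300,160,NA,23.628
C1,0.6,0.404,0.63,NA,17.721
C2,0.7,0.508,1.10,NA,17.721
C3,0.5,0.363,0.45,NA,17.721
C4,0.5,0.366,0.47,NA,17.721
C5,0.5,0.371,0.49,NA,17.721
C6,0.6,0.439,0.69,NA,17.721
C7,0.7,0.505,1.19,NA,17.721
T1,1.1,0.811,0.498,4.49,35.442
T2,1.1,0.780,1.32,4.49,35.442
T3,1.4,0.976,3.96,4.80,35.442
T4,1.3,0.920,7.22,3.68,35.442
T5,1.3,0.945,10.6,2.66,53.163
T6,1.3,0.932,13.9,1.33,53.163
T7,1.4,0.976,18.3,0.486,53.163
T8,1.5,1.049,22.2,0.170,53.163
T9,1.6,1.096,23.9,0.011,59.069
T10,2.0,1.419,29.9,0.057,59.069
T11,2.1,1.479,28.8,0.370,59.069
T12,2.5,1.767,29.7,0.867,59.069
L1,2.4,1.677,20.8,0.612,47.256
L2,2.4,1.689,12.4,0.272,41.349
L3,2.3,1.670,5.27,NA,35.442
L4,2.6,0.180,0.218,NA,NA
L5,2.6,0.182,0.0292,NA,NA
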