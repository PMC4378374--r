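# Default parameterization of the size-structured plankton food web.
#
# Allometric rules are log10-linear: log10(trait) = a + b * log10(V [um^3]).
# Numeric constants are assembled from the published size-scaling literature:
# nutrient uptake / half-saturation / quota exponents after Litchman et al.
# (2007, Ecol. Lett. 10:1170), cellular carbon content after Menden-Deuer &
# Lessard (2000, Limnol. Oceanogr. 45:569), and the four-functional-type
# structure (type-specific mu_max intercepts, Prochlorococcus nitrate
# exclusion) after Ward et al. (2012, Limnol. Oceanogr. 57:1877). They are
# defaults, not a fit: every value here can be overridden from user YAML.
#
# Units: volumes um^3; rates d^-1; quotas mol N (mol C)^-1; concentrations
# mmol (N or C) m^-3; depths m; irradiance W m^-2; temperature degC.

functional_types:
  Prochlorococcus:
    volume_range: [0.1, 1.0]
    can_use_nitrate: false
    mu_max: {a: -0.097, b: -0.1}     # 0.8 d^-1 at 1 um^3
  Synechococcus:
    volume_range: [0.5, 50.0]
    can_use_nitrate: true
    mu_max: {a: 0.0, b: -0.1}        # 1.0 d^-1 at 1 um^3
  small-eukaryote:
    volume_range: [10.0, 1.0e+4]
    can_use_nitrate: true
    mu_max: {a: 0.097, b: -0.1}      # 1.25 d^-1 at 1 um^3
  diatom:
    volume_range: [500.0, 1.0e+7]
    can_use_nitrate: true
    mu_max: {a: 0.204, b: -0.1}      # 1.6 d^-1 at 1 um^3

# Shared allometric rules (applied within every functional type).
# V_max and the quotas are per unit carbon biomass: per-cell scalings
# (V^0.67 uptake, V^0.84 quota) divided by per-cell carbon (V^0.94).
allometry:
  V_max: {a: -0.301, b: -0.27}          # mol N (mol C)^-1 d^-1; 0.5 at 1 um^3
  K_N: {a: -0.824, b: 0.33}             # mmol N m^-3; 0.15 at 1 um^3
  Q_min: {a: -1.301, b: -0.07}          # mol N (mol C)^-1; 0.05 at 1 um^3
  Q_max: {a: -0.770, b: -0.07}          # mol N (mol C)^-1; 0.17 at 1 um^3
  sinking: {a: -2.3, b: 0.28}           # m d^-1; ~1.3 m/d at 10^7 um^3
  carbon_per_cell: {a: -10.745, b: 0.94} # mmol C cell^-1 (Menden-Deuer & Lessard)

# Zooplankton size spectrum: 9 grazers whose log-normal prey kernels tile the
# whole phytoplankton size range (peak prey volumes 10^-1 .. 10^7 um^3).
zooplankton:
  n_species: 9
  volume_min: 1.0e+2
  volume_max: 1.0e+10
  rho_opt: 1000.0        # optimal predator:prey volume ratio (10x linear size)
  sigma: 0.6             # log-normal kernel width (ln-volume units)
  I_max: {a: 0.784, b: -0.12}  # d^-1; 3.5 at 10^2 um^3, 0.38 at 10^10 um^3
  assimilation: 0.7
  quota: 0.15            # fixed zoo N:C (mol N / mol C)
  mortality: 0.05        # linear background closure, d^-1
  k_A: 0.5               # Holling III half-saturation on availability, mmol C m^-3
  static: false          # hold grazer biomass fixed (prescribed log-periodic
                         # grazing background; no intra-guild predation)
  static_biomass: 0.5    # uniform grazer biomass when static, mmol C m^-3

ecology:
  mortality: 0.05        # size-independent phytoplankton death rate m, d^-1
  psi_NH4: 1.5           # ammonium inhibition of NO3/NO2 uptake, (mmol N m^-3)^-1
  f_DOM: 0.5             # fraction of mortality/egestion routed to dissolved pools
  remin_DOM: 0.06        # DON -> NH4 and DOC -> DIC, d^-1
  remin_POM: 0.03        # PON -> NH4 and POC -> DIC, d^-1
  nitrif_NH4: 0.10       # NH4 -> NO2, d^-1
  nitrif_NO2: 0.20       # NO2 -> NO3, d^-1
  w_detritus: 10.0       # POM sinking, m d^-1
  quasi_extinction_floor: 1.0e-15   # immigration floor, mmol C m^-3 per level

light:
  I_sat: 25.0            # growth light saturation, W m^-2
  k_water: 0.04          # background attenuation, m^-1
  k_chl: 0.03            # chlorophyll self-shading, m^-1 (mg chl m^-3)^-1
  theta_min: 0.05        # chl:C acclimation floor, mg chl (mmol C)^-1
  theta_max: 0.6         # chl:C acclimation ceiling
  theta_I_half: 30.0     # irradiance at mid acclimation, W m^-2

temperature:
  coeff: 0.0633          # Eppley exponential coefficient, degC^-1
  T_ref: 10.0            # gamma_T = 1 at T_ref

# Seasonal forcing emulating a high-latitude (Norwegian Sea like) column:
# strong annual light cycle, winter (Dec-Mar) convective mixing, summer
# stratification. Day 1 is January 1; the year has 365 days.
forcing:
  I0_mean: 101.0         # surface irradiance, W m^-2 (min 2, max 200)
  I0_amp: 99.0
  T_surf_mean: 8.0       # degC (4 .. 12 over the year)
  T_surf_amp: 4.0
  T_deep: 2.0
  z_T: 150.0             # thermocline e-folding depth, m
  mld_min: 30.0          # summer mixed-layer depth, m
  mld_max: 600.0         # late-winter mixed-layer depth, m
  mld_peak_day: 15       # day of deepest mixing
  mld_sharpness: 4.0     # cosine power shaping the winter convection season
  kappa_mixed: 1.0e+4    # mixed-layer diffusivity, m^2 d^-1
  kappa_bg: 0.9          # interior background diffusivity, m^2 d^-1
  kappa_width: 20.0      # vertical transition width at the mixed-layer base, m

grid:
  n_levels: 35
  depth: 3275.0
  stretch: 1.1           # geometric level-thickness ratio (fine near surface)

numerics:
  dt_bio: 0.05           # biological time step, d
  days_per_year: 365

initial:
  NO3: 12.0
  NO2: 0.01
  NH4: 0.01
  DIC: 2100.0
  plankton: 6.0e-9       # uniform seed biomass, mmol C m^-3

evolution:
  mutation_step: 0.10    # fractional cell-volume step of the two mutants
  eval_years: 1
  relax_years: 2
  mutant_amplitude: 1.0e-6

diagnostics:
  n_size_classes: 100
  size_range: [0.1, 1.0e+7]
  extinction_threshold: 1.0e-3   # mmol C m^-2 column-integrated
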