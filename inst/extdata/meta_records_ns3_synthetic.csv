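# units: latitude degN; SST degC; annRA fraction; peak_jd approximate Julian day
# Nova Scotia is split into its three regional groupings (inner, south, north),
# three replicate populations each. The per-population annRA values are
# SYNTHETIC stand-ins (the original study published only the overall mean,
# 0.56, which these rows reproduce on average); they exist to exercise the
# regional-grouping rule that yields the 11-point annRA layout.
region_id,latitude_degN,sst_mean_C,annRA,peak_month,peak_jd,measure,source
portugal,42.0,NA,0.76,11,NA,annRA,literature:araujo
new-england,43.0,NA,0.53,NA,NA,RE,literature:mathieson-guo
maine,45.0,NA,0.61,NA,NA,annRA,literature:vadas
nova-scotia-inner,44.6,NA,0.60,NA,NA,annRA,literature:cousens
nova-scotia-inner,44.7,NA,0.62,NA,NA,annRA,literature:cousens
nova-scotia-inner,44.5,NA,0.58,NA,NA,annRA,literature:cousens
nova-scotia-south,43.8,NA,0.55,NA,NA,annRA,literature:cousens
nova-scotia-south,43.7,NA,0.57,NA,NA,annRA,literature:cousens
nova-scotia-south,43.9,NA,0.53,NA,NA,annRA,literature:cousens
nova-scotia-north,45.6,NA,0.51,NA,NA,annRA,literature:cousens
nova-scotia-north,45.7,NA,0.54,NA,NA,annRA,literature:cousens
nova-scotia-north,45.5,NA,0.54,NA,NA,annRA,literature:cousens
france,48.0,NA,0.54,2,NA,annRA,literature:araujo
sweden,58.5,NA,0.53,NA,NA,annRA,literature:aberg
hirsholmene,57.75,NA,0.51,4,NA,annRA,field:denmark-2024
kobbefjord,64.2333,NA,0.50,7,NA,annRA,field:greenland-2023
kronprinsen,69.0333,NA,0.33,8,NA,annRA,field:greenland-2023
qeqertarsuaq,69.4,NA,0.39,8,NA,annRA,field:greenland-2023
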