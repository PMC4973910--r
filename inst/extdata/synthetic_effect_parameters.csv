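param,sex,age_band,value,spread
beta_chol,male,25-34,0.30071562116502154,0.045107343174753234
beta_chol,male,35-44,0.27337783742274685,0.04100667561341203
beta_chol,male,45-54,0.22963738343510734,0.034445607515266104
beta_chol,male,55-64,0.18589692944746788,0.027884539417120182
beta_chol,male,65-74,0.1476240322082833,0.022143604831242496
beta_chol,male,75-84,0.10935113496909875,0.016402670245364813
beta_sbp,male,25-34,0.05263390592005121,0.007895085888007681
beta_sbp,male,35-44,0.04678569415115663,0.007017854122673495
beta_sbp,male,45-54,0.038598197674704224,0.005789729651205633
beta_sbp,male,55-64,0.03041070119825181,0.004561605179737771
beta_sbp,male,65-74,0.023392847075578316,0.0035089270613367475
beta_sbp,male,75-84,0.017544635306683737,0.0026316952960025604
rr_smoking,male,25-34,3.6207183211682117,0.12
rr_smoking,male,35-44,2.9218601021900223,0.12
rr_smoking,male,45-54,2.310359160584106,0.12
rr_smoking,male,55-64,1.8735727737227372,0.12
rr_smoking,male,65-74,1.611500941605916,0.12
rr_smoking,male,75-84,1.349429109489095,0.12
rr_inactivity,male,25-34,1.8705749059376586,0.12
rr_inactivity,male,35-44,1.7835174153438929,0.12
rr_inactivity,male,45-54,1.652931179453244,0.12
rr_inactivity,male,55-64,1.522344943562595,0.12
rr_inactivity,male,65-74,1.3917587076719464,0.12
rr_inactivity,male,75-84,1.2611724717812975,0.12
beta_chol,female,25-34,0.31710720174848034,0.04756608026227205
beta_chol,female,35-44,0.2882792743168003,0.04324189114752004
beta_chol,female,45-54,0.24215459042611223,0.036323188563916836
beta_chol,female,55-64,0.1960299065354242,0.02940448598031363
beta_chol,female,65-74,0.15567080813107217,0.023350621219660823
beta_chol,female,75-84,0.11531170972672011,0.01729675645900802
beta_sbp,female,25-34,0.053285566730367794,0.00799283500955517
beta_sbp,female,35-44,0.04736494820477138,0.007104742230715706
beta_sbp,female,45-54,0.039076082268936385,0.005861412340340458
beta_sbp,female,55-64,0.030787216333101393,0.004618082449965209
beta_sbp,female,65-74,0.02368247410238569,0.003552371115357853
beta_sbp,female,75-84,0.017761855576789266,0.0026642783365183895
rr_smoking,female,25-34,5.168781275867763,0.12
rr_smoking,female,35-44,4.057106268969694,0.12
rr_smoking,female,45-54,3.0843906379338817,0.12
rr_smoking,female,55-64,2.3895937586225875,0.12
rr_smoking,female,65-74,1.9727156310358114,0.12
rr_smoking,female,75-84,1.5558375034490348,0.12
rr_inactivity,female,25-34,1.9746324543388418,0.12
rr_inactivity,female,35-44,1.8771692089049576,0.12
rr_inactivity,female,45-54,1.7309743407541314,0.12
rr_inactivity,female,55-64,1.584779472603305,0.12
rr_inactivity,female,65-74,1.4385846044524788,0.12
rr_inactivity,female,75-84,1.2923897363016525,0.12
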