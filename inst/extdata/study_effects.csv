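study,label,kind,estimate,se,n
study1,tickets_mean,mean,1508.7,63.2,60
study2,tickets_mean,mean,1418.8,60.8,76
study1,dmx_mean,mean,53.1,1.4,60
study2,dmx_mean,mean,51.1,1.6,76
study1,tickets_age,fisher_z,-0.328,0.132,60
study2,tickets_age,fisher_z,-0.149,0.117,76
study1,tickets_dmx,fisher_z,0.682,0.132,60
study2,tickets_dmx,fisher_z,0.841,0.117,76
study1,tickets_games,fisher_z,0.487,0.132,60
study2,tickets_games,fisher_z,0.329,0.117,76
study1,tickets_switches,fisher_z,0.755,0.132,60
study2,tickets_switches,fisher_z,0.616,0.117,76
study1,tickets_crt,fisher_z,0.334,0.132,60
study2,tickets_crt,fisher_z,0.182,0.117,76
study1,tickets_aomtb,fisher_z,0.019,0.132,60
study2,tickets_aomtb,fisher_z,0.194,0.117,76
study1,tickets_ncs,fisher_z,-0.022,0.132,60
study2,tickets_ncs,fisher_z,0.267,0.117,76
study1,dmx_age,fisher_z,-0.132,0.132,60
study2,dmx_age,fisher_z,-0.171,0.117,76
study1,dmx_games,fisher_z,0.261,0.132,60
study2,dmx_games,fisher_z,0.423,0.117,76
study1,dmx_switches,fisher_z,0.495,0.132,60
study2,dmx_switches,fisher_z,0.557,0.117,76
study1,dmx_crt,fisher_z,0.063,0.132,60
study2,dmx_crt,fisher_z,0.021,0.117,76
study1,dmx_aomtb,fisher_z,-0.141,0.132,60
study2,dmx_aomtb,fisher_z,0.102,0.117,76
study1,dmx_ncs,fisher_z,-0.091,0.132,60
study2,dmx_ncs,fisher_z,-0.066,0.117,76
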