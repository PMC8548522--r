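"track_id","group_id","frame","time_s","x","y","sigma_x","sigma_y"
"locus1","cell1",0,0,-0.0290458164319914,0.0958815534292026,0.1,0.1
"locus1","cell1",1,0.5,-0.171842026723262,-0.673126757535047,0.1,0.1
"locus1","cell1",2,1,0.0575478953952002,0.615538390160125,0.1,0.1
"locus1","cell1",3,1.5,-0.501633371588699,-0.820391503199274,0.1,0.1
"locus1","cell1",5,2.5,0.153528495702367,-0.713384475566815,0.1,0.1
"locus1","cell1",6,3,0.952476585501011,-1.23091125583653,0.1,0.1
"locus1","cell1",7,3.5,1.34033469451279,-1.11290070352297,0.1,0.1
"locus1","cell1",8,4,1.10447617627407,-1.72699393594615,0.1,0.1
"locus1","cell1",9,4.5,1.59482250168763,-3.22441114141309,0.1,0.1
"locus1","cell1",10,5,1.38639287802487,-3.0859292390486,0.1,0.1
"locus1","cell1",11,5.5,1.68555504976509,-2.63024324360501,0.1,0.1
"locus2","cell1",0,0,0.0190617673609224,-0.0474222694205301,0.1,0.1
"locus2","cell1",1,0.5,0.148298289807269,0.140290549063967,0.1,0.1
"locus2","cell1",2,1,0.835891436220895,-0.630248372174149,0.1,0.1
"locus2","cell1",3,1.5,-0.462264374690669,-1.53421137245251,0.1,0.1
"locus2","cell1",4,2,1.36796120732312,-1.98724526942625,0.1,0.1
"locus2","cell1",6,3,3.85470279281989,-3.77685941903269,0.1,0.1
"locus2","cell1",7,3.5,4.73895998585048,-2.1028542658939,0.1,0.1
"locus2","cell1",8,4,5.27249867215278,-3.90323144420422,0.1,0.1
"locus2","cell1",9,4.5,5.90994901260535,-3.37477257828736,0.1,0.1
"locus2","cell1",10,5,7.53701483323192,-2.71129658367269,0.1,0.1
"locus2","cell1",11,5.5,9.08932034703162,-2.76320308877497,0.1,0.1
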