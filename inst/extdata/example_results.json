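{"software":"fbmtrack","version":"1.0.0","seed":103,"settings":{"min_points":5},"tracks":[{"track_id":"locus1","D_alpha":0.518546587069323,"alpha":0.829988506594054,"mu":[-0.741300780922673,0.311766752719399],"log_posterior":-89.0215925888822,"n_used":39,"flagged":false}],"groups":[]}
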