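category,area_pct,top20_pct,top10_pct
Private,53,55,55
Bureau of Land Management,16,24,25
U.S. Forest Service,14,8,7
Tribal,7,4,4
State,5,8,8
Other,2,1,1
National Park Service,2,NA,NA
U.S. Fish and Wildlife Service,1,NA,NA
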