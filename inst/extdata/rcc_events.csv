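label,start_ka,end_ka,reference
Meltwater pulse 1A,14.9,13.9,Harrison et al.
14.8 ka climate shifts,14.8,14.8,multiple
Lake Agassiz Herman outburst,12.9,12.9,Teller et al.
Lake Agassiz Norcross outburst,11.7,11.7,Teller et al.
11.4 ka warm excursion,11.4,11.4,multiple
Lake Agassiz Tintah outburst,11.2,11.2,Teller et al.
Lake Agassiz Upper Campbell outburst,10.6,10.6,Teller et al.
Meltwater pulse 1C,9.8,9.8,Harrison et al.
9 to 8 ka Glacial Aftermath,8.8,8.0,Mayewski et al.
9.2 ka event,9.5,9.2,multiple
8.2 ka event,8.2,8.2,multiple
7.6 ka event,7.6,7.4,multiple
7.2 ka event,7.6,7.0,multiple
6.4 ka event,6.4,6.4,multiple
5.5 ka event,5.5,5.5,multiple
5.3 ka event,5.3,5.3,multiple
4.8 warm excursion,4.8,4.8,multiple
4.2 ka event,4.2,4.0,multiple
3.6 ka event,3.6,3.4,multiple
3.0 to 2.3 ka event,3.0,2.3,multiple
2.8 ka event,2.8,2.71,multiple
2.1 ka event,2.3,2.0,multiple
Roman Warm Period (RWP),2.0,1.3,multiple
1.6 ka cold excursion,1.6,1.6,multiple
Late Antique Little Ice Age (LALIA),1.6,1.3,multiple
1.4 ka event,1.4,1.4,multiple
1.0 ka warm excursion,1.0,1.0,multiple
Little Ice Age (LIA),0.75,0.1,multiple
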