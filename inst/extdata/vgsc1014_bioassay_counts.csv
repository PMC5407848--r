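insecticide,outcome,group_fine,genotype,count
DDT,alive,Leu/Leu,TTA/TTA,3
DDT,alive,Leu/Ser,TCA/TTA,4
DDT,alive,Leu/Phe,TTA/TTT,2
DDT,alive,Ser/Ser,TCA/TCA,28
DDT,alive,Ser/Phe,TCA/TTT,33
DDT,alive,Phe/Phe,TTT/TTT,13
DDT,dead,Leu/Leu,TTA/TTA,20
DDT,dead,Leu/Ser,TCA/TTA,32
DDT,dead,Leu/Phe,TTA/TTT,10
DDT,dead,Ser/Ser,TCA/TCA,15
DDT,dead,Ser/Phe,TCA/TTT,6
DDT,dead,Phe/Phe,TTT/TTT,0
deltamethrin,alive,Leu/Leu,TTA/TTA,0
deltamethrin,alive,Leu/Ser,TCA/TTA,0
deltamethrin,alive,Leu/Phe,TTA/TTT,11
deltamethrin,alive,Ser/Ser,TCA/TCA,11
deltamethrin,alive,Ser/Phe,TCA/TTT,18
deltamethrin,alive,Phe/Phe,TTT/TTT,7
deltamethrin,dead,Leu/Leu,TTA/TTA,6
deltamethrin,dead,Leu/Ser,TCA/TTA,12
deltamethrin,dead,Leu/Phe,TTA/TTT,18
deltamethrin,dead,Ser/Ser,TCA/TCA,8
deltamethrin,dead,Ser/Phe,TCA/TTT,16
deltamethrin,dead,Phe/Phe,TTT/TTT,2
alpha-cypermethrin,alive,Leu/Leu,TTA/TTA,0
alpha-cypermethrin,alive,Leu/Ser,TCA/TTA,3
alpha-cypermethrin,alive,Leu/Phe,TTA/TTT,0
alpha-cypermethrin,alive,Ser/Ser,TCA/TCA,13
alpha-cypermethrin,alive,Ser/Phe,TCA/TTT,5
alpha-cypermethrin,alive,Phe/Phe,TTT/TTT,2
alpha-cypermethrin,dead,Leu/Leu,TTA/TTA,57
alpha-cypermethrin,dead,Leu/Ser,TCA/TTA,51
alpha-cypermethrin,dead,Leu/Phe,TTA/TTT,11
alpha-cypermethrin,dead,Ser/Ser,TCA/TCA,15
alpha-cypermethrin,dead,Ser/Phe,TCA/TTT,2
alpha-cypermethrin,dead,Phe/Phe,TTT/TTT,1
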